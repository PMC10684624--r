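# Silylation reagent registry. site_delta is the NET composition change
# per derivatized site: the silyl group minus the acidic proton it
# replaces (TBDMS: -H +C6H15Si = +C6H14Si). ei_losses are characteristic
# alpha-cleavage radical losses; `generic: true` marks losses that are
# also seen for underivatized (Si-free) species, while non-generic
# losses require at least one installed silyl group.
TBDMS:
  name: TBDMS
  description: tert-butyldimethylsilyl (installed by MTBSTFA)
  site_delta: C6H14Si
  target_groups: [hydroxyl, thiol, amine]
  ei_losses:
    - label: CH3
      formula: CH3
      generic: true
    - label: C4H9
      formula: C4H9
      generic: false
  reporter_ion_mz: ~
TMS:
  name: TMS
  description: trimethylsilyl (installed by BSTFA/TMCS)
  site_delta: C3H8Si
  target_groups: [hydroxyl, thiol, amine]
  ei_losses:
    - label: CH3
      formula: CH3
      generic: true
  reporter_ion_mz: 73.0468
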