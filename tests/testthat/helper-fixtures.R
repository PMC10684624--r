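# Shared fixtures: published candidate lists, a brute-force enumeration
# oracle, and a random-formula generator for property-style tests.

# The fifteen vendor-assigned ion compositions for the glycosylated
# flavonoid case study: underivatized [M+H]+ plus the once- and
# four-times TBDMS-derivatized ions.
table2_ions <- function() {
  candidates_from_table(list(
    list(degree = 0, mz = 379.1179,
         formulas = c("C22H19O6", "C29H15O", "C11H23O14",
                      "C15H23O11", "C18H19O9")),
    list(degree = 1, mz = 493.2097,
         formulas = c("C28H33O6Si", "C35H29OSi", "C17H37O14Si",
                      "C21H37O11Si", "C32H33O3Si")),
    list(degree = 4, mz = 835.4821,
         formulas = c("C50H75O3Si4", "C43H79O8Si4", "C36H83O13Si4",
                      "C39H79O11Si4", "C54H75Si4"))
  ))
}

quercetin <- "C15H10O7"
ted13 <- "C14H10O6"
ztf <- "C15H22O11"

# Independent enumeration oracle: exhaustive grid over the bound box,
# nothing shared with the recursive implementation.
brute_enumerate <- function(m_lo, m_hi, bounds) {
  et <- element_table()
  masses <- setNames(et$monoisotopic_mass, et$symbol)
  grid <- do.call(expand.grid, lapply(bounds, function(b) b[1]:b[2]))
  total <- as.vector(as.matrix(grid) %*% masses[names(bounds)])
  keep <- which(total >= m_lo & total <= m_hi & rowSums(grid) > 0)
  out <- vapply(keep, function(i) {
    counts <- as.integer(grid[i, ])
    present <- counts > 0
    format(parse_formula(paste0(names(bounds)[present], counts[present],
                                collapse = "")))
  }, character(1))
  sort(out)
}

# Random plausible CHO natural-product-like parent with n_sites hydroxyls.
random_parent <- function(n_sites) {
  c_n <- sample(8:20, 1)
  h_n <- sample(max(n_sites, 6):(2 * c_n), 1)
  o_n <- n_sites + sample(0:3, 1)
  parse_formula(sprintf("C%dH%dO%d", c_n, h_n, o_n))
}

random_formula <- function() {
  syms <- c("C", "H", "O", "Si", "N")
  counts <- c(sample(1:20, 1), sample(1:30, 1), sample(0:8, 1),
              sample(0:3, 1), sample(0:2, 1))
  present <- counts > 0
  parse_formula(paste0(syms[present], counts[present], collapse = ""))
}
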