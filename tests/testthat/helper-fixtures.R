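# Fixtures are built in code at test time; nothing is read from disk except
# files the tests themselves write to tempdir().

# Exact straight-line CS records: response = intercept + slope * conc
make_cs <- function(levels = c(5, 25, 75, 125, 175, 250), series = 1L,
                    intercept = 0.1, slope = 0.02, analyte = "AFA",
                    reps = 1L) {
  g <- expand.grid(rep = seq_len(reps), nominal_conc = levels)
  data.frame(analyte = analyte, role = "CS", series = series,
             level = match(g$nominal_conc, levels),
             nominal_conc = g$nominal_conc,
             response = intercept + slope * g$nominal_conc,
             conc = NA_real_)
}

# Balanced VS records at one level with given back-calculated concentrations
make_vs <- function(conc, p, n, nominal = 5, level = 1L, analyte = "AFA") {
  data.frame(analyte = analyte, role = "VS",
             series = rep(seq_len(p), each = n), level = level,
             nominal_conc = nominal, response = NA_real_, conc = conc)
}

# Brute-force one-way ANOVA oracle: two-pass sums over the raw cells,
# written independently of variance_components()
vc_oracle <- function(x) {
  p <- nrow(x); n <- ncol(x)
  gm <- sum(x) / (p * n)
  row_means <- apply(x, 1, function(r) sum(r) / n)
  ssb <- 0
  for (i in seq_len(p)) ssb <- ssb + n * (row_means[i] - gm)^2
  ssw <- 0
  for (i in seq_len(p)) for (j in seq_len(n))
    ssw <- ssw + (x[i, j] - row_means[i])^2
  msb <- ssb / (p - 1)
  msw <- ssw / (p * (n - 1))
  list(s2_within = msw, s2_between = (msb - msw) / n)
}

# Published summary table for one analyte, from the packaged dataset
summary_afa <- function() tki_plasma_summary("AFA")
summary_ibr <- function() tki_plasma_summary("IBR")
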