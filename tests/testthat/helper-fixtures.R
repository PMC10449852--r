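# Frozen reference values for the landscape dG1 = -25, dGT = -40 kJ/mol,
# alpha1 = alpha2 = 0.5, k1_0 = k2_0 = 1, T = 298.15 K, computed once with an
# independent 40-digit evaluation of the exponential forms.
oracle_landscape <- list(
  dG1 = -25, dGT = -40,
  k1  = 154.89132952109637,
  k1r = 0.0064561393016114495,
  k2  = 20.607070863516536,
  k2r = 0.048527032620168946,
  Km  = 0.13308380182772311,
  haldane = 10187948.577852515,   # exp(40/RT)
  v_S10_ET0.01 = 0.20336425975081348
)

# small CSV Km-[S] table written to a temp file; returns the path
write_toy_table <- function(rows, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  header <- paste(c("substrate", "Km", "S", "organism"), collapse = sep)
  lines <- vapply(rows, function(r) paste(r, collapse = sep), character(1))
  writeLines(c(header, lines), path)
  path
}
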