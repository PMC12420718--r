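# Small builders used across the suite.

make_comparison <- function(name, gene_id, log2fc, p_value = NULL,
                            annotation = NULL) {
  n <- length(gene_id)
  comparison(name, tibble::tibble(
    gene_id = gene_id,
    log2fc = log2fc,
    p_value = if (is.null(p_value)) rep(NA_real_, n) else p_value,
    annotation = if (is.null(annotation)) rep(NA_character_, n) else
      annotation
  ))
}

# a tiny deterministic two-scorecard collection with hand-placed genes
tiny_collection <- function(cfg = scorecard_config(2, 3, alpha = 0.05)) {
  c1 <- make_comparison("A", c("g1", "g2", "g3", "g4"),
                        c(3.5, 2.5, -3.95, 0.5),
                        c(0.01, 0.02, 0.03, 0.9),
                        c("ABC transporter permease", "nitrate reductase",
                          "ABC transporter ATPase", NA))
  c2 <- make_comparison("B", c("g1", "g2", "g3", "g4"),
                        c(3.2, 3.6, -1.98, 0.2),
                        c(0.001, 0.04, 0.5, 0.8),
                        c("ABC transporter permease", NA, NA, NA))
  c3 <- make_comparison("C", c("g1", "g2", "g3", "g4"),
                        c(0.1, -2.5, 0.3, 0.0),
                        c(0.5, 0.01, 0.9, 0.9))
  build_scorecards(list(c1, c2, c3), cfg)
}

write_fixture_csv <- function(path) {
  writeLines(c(
    "gene,fc_A,p_A,fc_B,p_B,desc",
    "g1,3.5,0.01,3.2,0.001,alpha protein",
    "g2,2.5,0.02,3.6,0.04,beta protein",
    "g3,-3.95,0.03,-1.98,0.5,gamma protein"
  ), path)
  path
}
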