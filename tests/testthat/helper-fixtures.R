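# small in-code fixtures

probe_df <- function(...) {
  rows <- list(...)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("probe", "gene", "gF", "gB", "rF", "rB")
  for (c4 in names(df)[3:6]) df[[c4]] <- as.numeric(df[[c4]])
  df
}

probe_map <- c(probe_id = "probe", gene_id = "gene", green_fg = "gF",
               green_bg = "gB", red_fg = "rF", red_bg = "rB")

expr_df <- function(ids, M, A) {
  data.frame(gene_id = ids, M = M, A = A, stringsAsFactors = FALSE)
}
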