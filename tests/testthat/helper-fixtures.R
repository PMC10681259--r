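# Small in-code fixtures.

toy_counts <- function(m, gene_ids = sprintf("g%d", seq_len(nrow(m))),
                       samples = sprintf("s%d", seq_len(ncol(m)))) {
  tbl <- tibble::as_tibble(as.data.frame(m))
  names(tbl) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), tbl)
}

toy_design <- function(n_input = 3, n_ip = 3) {
  tibble::tibble(
    sample = c(sprintf("s%d", seq_len(n_input)),
               sprintf("s%d", n_input + seq_len(n_ip))),
    condition = rep(c("input", "IP"), c(n_input, n_ip)),
    replicate = c(seq_len(n_input), seq_len(n_ip))
  )
}

# protein-group table at a chosen stage, from a groups x samples matrix
# (NA = missing on the log2 stages, 0 = not quantified on the raw stage)
toy_protein_table <- function(m, stage = "raw",
                              razor = rep(5L, nrow(m)),
                              reverse = rep(FALSE, nrow(m)),
                              contaminant = rep(FALSE, nrow(m)),
                              samples = colnames(m)) {
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  tbl <- tibble::as_tibble(as.data.frame(m))
  names(tbl) <- samples
  out <- dplyr::bind_cols(
    tibble::tibble(group_id = sprintf("grp%d", seq_len(nrow(m))),
                   razor_unique_peptides = razor,
                   reverse = reverse, contaminant = contaminant),
    tbl
  )
  attr(out, "lfq_stage") <- stage
  out
}

toy_protein_design <- function(n_bait = 6, n_control = 3) {
  tibble::tibble(
    sample = c(sprintf("b%d", seq_len(n_bait)),
               sprintf("c%d", seq_len(n_control))),
    group = rep(c("bait", "control"), c(n_bait, n_control))
  )
}
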