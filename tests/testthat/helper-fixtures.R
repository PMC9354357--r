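# shared fixtures, all generated in code

design3 <- function() {
  study_design(c("study1", "study2", "study3"),
               cases = c(10, 15, 12), controls = c(10, 10, 16))
}

equal_design <- function(n_studies = 2, n = 5) {
  study_design(paste0("s", seq_len(n_studies)),
               cases = rep(n, n_studies), controls = rep(n, n_studies))
}

# evidence table built directly from per-study p / log2FC vectors;
# a list entry of NULL marks the gene absent in that study
toy_evidence <- function(p_list, lfc_list, design) {
  genes <- names(p_list)
  tabs <- lapply(seq_len(nrow(design)), function(s) {
    keep <- vapply(genes, function(g) !is.na(p_list[[g]][s]), logical(1))
    data.frame(gene = genes[keep],
               pvalue = vapply(genes[keep], function(g) p_list[[g]][s], 1),
               log2FC = vapply(genes[keep], function(g) lfc_list[[g]][s], 1),
               stringsAsFactors = FALSE)
  })
  assemble_evidence(stats::setNames(tabs, design$study), design)
}

# small NB count matrix with a known fraction of DE genes
# (directions alternate up/down so normalization stays composition-neutral)
toy_counts <- function(G = 400, n_per_group = 6, de_frac = 0.1, lfc = 2,
                       phi = 0.1, mu = 100, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  n_de <- round(de_frac * G)
  dirs <- rep_len(c(1, -1), n_de)
  means <- matrix(mu, G, n)
  if (n_de > 0)
    means[seq_len(n_de), seq_len(n_per_group)] <- mu * 2^(dirs * lfc)
  counts <- matrix(stats::rnbinom(G * n, mu = means, size = 1 / phi), G, n)
  rownames(counts) <- paste0("g", seq_len(G))
  colnames(counts) <- c(paste0("case", 1:n_per_group),
                        paste0("ctrl", 1:n_per_group))
  list(counts = counts,
       labels = rep(c("case", "control"), each = n_per_group),
       de_genes = paste0("g", seq_len(n_de)),
       de_directions = dirs)
}
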