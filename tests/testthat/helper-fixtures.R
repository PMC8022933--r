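# Small programmatic fixtures shared across test files.

# balanced toy phenotype: cc clones x b blocks x k trees, m time points,
# heights = base + clone effect + noise
make_toy_pheno <- function(cc = 4, b = 2, k = 2, m = 2, seed = 1,
                           base = 50, clone_sd = 2, noise_sd = 1) {
  set.seed(seed)
  clones <- paste0("C", seq_len(cc))
  grid <- expand.grid(clone = clones, block = paste0("B", seq_len(b)),
                      tree = paste0("t", seq_len(k)),
                      stringsAsFactors = FALSE)
  g <- stats::rnorm(cc, 0, clone_sd)
  tp <- paste0("T", seq_len(m))
  long <- do.call(rbind, lapply(seq_len(m), function(t_) {
    data.frame(grid,
               timepoint = tp[t_],
               height = base + 5 * (t_ - 1) +
                 g[match(grid$clone, clones)] +
                 stats::rnorm(nrow(grid), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  pheno_table(long, tp)
}

# alternating two-class calls over a clone set
make_toy_calls <- function(clones, classes = c("aa", "ab")) {
  stats::setNames(rep(classes, length.out = length(clones)), clones)
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

table2_fixture <- function() {
  f <- system.file("extdata", "significant_height_snps.tsv",
                   package = "clonescan")
  utils::read.table(f, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
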