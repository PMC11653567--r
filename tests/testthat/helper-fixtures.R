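# shared fixtures built in code

# sample table for one cross: 4 genotypes x 2 sexes x reps
toy_samples <- function(reps = 3, lines = c("A", "B"), cross = "I") {
  cells <- expand.grid(replicate = seq_len(reps),
                       sex = c("female", "male"),
                       genotype = c(paste0(lines[1], lines[1]),
                                    paste0(lines[2], lines[2]),
                                    paste0(lines[1], lines[2]),
                                    paste0(lines[2], lines[1])),
                       stringsAsFactors = FALSE)
  cells$dam <- substr(cells$genotype, 1, 1)
  cells$sire <- substr(cells$genotype, 2, 2)
  cells$cross <- cross
  cells$sample_id <- sprintf("%s_%s_%s_r%d", cross, cells$genotype,
                             ifelse(cells$sex == "female", "F", "M"),
                             cells$replicate)
  make_sample_table(cells[, c("sample_id", "sex", "dam", "sire",
                              "cross", "replicate")])
}

# normalized matrix with exact per-(genotype, sex) means, no noise
toy_norm <- function(samples, means) {
  # means: named list, e.g. list(AA_female = 10, ...)
  m <- matrix(NA_real_, nrow = length(means[[1]]), ncol = nrow(samples),
              dimnames = list(sprintf("g%03d", seq_along(means[[1]])),
                              samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    key <- paste(samples$genotype[j], samples$sex[j], sep = "_")
    m[, j] <- means[[key]]
  }
  m
}

# single-cross simulation config used by several files
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 150, crosses = list(c("A", "B")),
         prop_x_linked = 0, prop_y_linked = 0),
    list(...))
  do.call(sim_config, args)
}
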