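#' Read a transcript-by-sample count matrix
#'
#' Reads a tab-separated count table (header row of sample identifiers,
#' first column of transcript identifiers) into a validated integer matrix.
#' Row and column order of the file are preserved.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("count table must have a gene-id column and at least one sample")
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  m <- matrix(NA_integer_, nrow = nrow(tab), ncol = length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad) > 0L)
      stop(sprintf(
        "non-integer or negative count '%s' at gene '%s', sample '%s'",
        col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
    m[, j] <- as.integer(num)
  }
  validate_counts(m)
}

#' @noRd
validate_counts <- function(counts) {
  if (!is.matrix(counts))
    stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers with no missing values")
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix as returned by [read_counts()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  tab <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate the sample design table
#'
#' Expects columns `sample_id`, `sex`, `dam`, `sire`, `cross`, `replicate`.
#' The genotype label is derived dam-first (`"AB"` means dam A, sire B), so
#' the two reciprocal heterozygotes of a cross get distinct labels and a
#' genotype is homozygous iff dam equals sire.
#'
#' @param path Path to a TSV file.
#' @param counts Optional count matrix; if supplied, sample ids must match
#'   one-to-one.
#' @return A `data.frame` with derived columns `genotype`, `homozygous`,
#'   `excluded` (FALSE) and `exclude_reason` (NA).
#' @export
read_samples <- function(path, counts = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "sex", "dam", "sire", "cross", "replicate")
  miss <- setdiff(req, colnames(tab))
  if (length(miss) > 0L)
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  make_sample_table(tab, counts)
}

#' Assemble a validated sample table from a data frame
#'
#' @param tab Data frame with columns `sample_id`, `sex`, `dam`, `sire`,
#'   `cross`, `replicate`.
#' @param counts Optional count matrix for one-to-one id checking.
#' @return Validated sample `data.frame` (see [read_samples()]).
#' @export
make_sample_table <- function(tab, counts = NULL) {
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample ids in sample table")
  bad_sex <- setdiff(unique(tab$sex), c("female", "male"))
  if (length(bad_sex) > 0L)
    stop("unknown sex token(s): ", paste(bad_sex, collapse = ", "),
         " (expected 'female' or 'male')")
  tab$replicate <- as.integer(tab$replicate)
  if (anyNA(tab$replicate) || any(tab$replicate < 1L))
    stop("replicate must be a positive integer")
  tab$genotype <- paste0(tab$dam, tab$sire)
  tab$homozygous <- tab$dam == tab$sire
  if (is.null(tab$excluded)) tab$excluded <- FALSE
  if (is.null(tab$exclude_reason)) tab$exclude_reason <- NA_character_
  if (!is.null(counts)) {
    only_counts <- setdiff(colnames(counts), tab$sample_id)
    only_table <- setdiff(tab$sample_id, colnames(counts))
    if (length(only_counts) > 0L || length(only_table) > 0L)
      stop("design error: sample ids do not match counts; ",
           if (length(only_counts)) paste0("only in counts: ",
             paste(only_counts, collapse = ", "), "; ") else "",
           if (length(only_table)) paste0("only in sample table: ",
             paste(only_table, collapse = ", ")) else "")
    tab <- tab[match(colnames(counts), tab$sample_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Validate a complete reciprocal-cross design
#'
#' A valid cross contains exactly four genotypes — two homozygous parental
#' lines and the two reciprocal heterozygotes — in both sexes with `r`
#' replicates per (genotype, sex) cell.
#'
#' @param samples Sample table (see [read_samples()]).
#' @return Invisibly TRUE; stops with a message listing missing cells
#'   otherwise.
#' @export
validate_design <- function(samples) {
  for (cr in unique(samples$cross)) {
    s <- samples[samples$cross == cr & !samples$excluded, , drop = FALSE]
    lines <- sort(unique(c(s$dam, s$sire)))
    if (length(lines) != 2L)
      stop(sprintf("cross '%s' must involve exactly 2 lines, found: %s",
                   cr, paste(lines, collapse = ", ")))
    want <- c(paste0(lines[1], lines[1]), paste0(lines[2], lines[2]),
              paste0(lines[1], lines[2]), paste0(lines[2], lines[1]))
    cells <- expand.grid(genotype = want, sex = c("female", "male"),
                         stringsAsFactors = FALSE)
    have <- paste(s$genotype, s$sex)
    missing <- cells[!(paste(cells$genotype, cells$sex) %in% have), ]
    if (nrow(missing) > 0L)
      stop(sprintf("cross '%s' missing design cell(s): %s", cr,
                   paste(paste(missing$genotype, missing$sex),
                         collapse = ", ")))
    n_cell <- table(have)
    if (length(unique(n_cell)) != 1L)
      stop(sprintf("cross '%s' is unbalanced: replicate counts %s", cr,
                   paste(sort(unique(n_cell)), collapse = "/")))
  }
  invisible(TRUE)
}

#' Write a sample table as TSV
#' @param samples Sample table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the gene annotation table
#'
#' Expects columns `gene_id` and `chrom_class` (one of `autosome`, `X`,
#' `Y`).
#'
#' @param path Path to a TSV file.
#' @param counts Optional count matrix; every gene in it must be annotated.
#' @return Data frame with columns `gene_id`, `chrom_class`.
#' @export
read_genes <- function(path, counts = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "chrom_class"), colnames(tab))
  if (length(miss) > 0L)
    stop("gene table missing columns: ", paste(miss, collapse = ", "))
  tab$gene_id <- as.character(tab$gene_id)
  if (anyDuplicated(tab$gene_id))
    stop("duplicated gene ids in gene table")
  bad <- setdiff(unique(tab$chrom_class), c("autosome", "X", "Y"))
  if (length(bad) > 0L)
    stop("unknown chrom_class token(s): ", paste(bad, collapse = ", "))
  if (!is.null(counts)) {
    unannotated <- setdiff(rownames(counts), tab$gene_id)
    if (length(unannotated) > 0L)
      stop("genes in counts without annotation: ",
           paste(utils::head(unannotated, 5L), collapse = ", "),
           if (length(unannotated) > 5L) ", ..." else "")
  }
  tab
}

#' Read a gene-to-GO mapping
#'
#' Two-column TSV (`gene_id`, `go_id`), one pair per line; duplicated pairs
#' are removed. GO identifiers must match `GO:` followed by seven digits.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `gene_id`, `go_id`.
#' @export
read_go_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("GO map must have two columns: gene_id, go_id")
  colnames(tab)[1:2] <- c("gene_id", "go_id")
  bad <- !grepl("^GO:[0-9]{7}$", tab$go_id)
  if (any(bad))
    stop("invalid GO identifier(s): ",
         paste(utils::head(unique(tab$go_id[bad]), 5L), collapse = ", "))
  unique(tab[, c("gene_id", "go_id")])
}

#' Write per-transcript dominance results as TSV
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces every double bit-identically.
#'
#' @param results Data frame of per-transcript results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path Path to the TSV.
#' @return Data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
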