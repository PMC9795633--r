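# Column layout of the variant table: fixed annotation columns followed by one
# "<sample_id>:mut" / "<sample_id>:tot" pair per sample. Counts are the primary
# data; frequencies are always derived, never stored.
VARIANT_INFO_COLS <- c("mutation_id", "contig", "position", "ref_allele",
                       "alt_allele", "gene", "mutation_class")

#' Sample identifiers declared by a variant table
#'
#' @param table a variant table (`data.frame`).
#' @return character vector of sample ids, in column order.
#' @export
variant_samples <- function(table) {
  cols <- colnames(table)
  mut <- sub(":mut$", "", grep(":mut$", cols, value = TRUE))
  tot <- sub(":tot$", "", grep(":tot$", cols, value = TRUE))
  if (!identical(mut, tot)) {
    missing <- c(setdiff(mut, tot), setdiff(tot, mut))
    stop("incomplete sample column pair(s) for: ", paste(missing, collapse = ", "))
  }
  mut
}

#' Assemble a variant table from annotations and count matrices
#'
#' @param info `data.frame` with columns `mutation_id`, `contig`, `position`,
#'   `ref_allele`, `alt_allele`, `gene`, `mutation_class`.
#' @param mutant,total integer matrices (mutations x samples) of reads
#'   supporting the mutant allele and of total reads covering the site;
#'   `total = 0` encodes a zero-coverage (masked) cell.
#' @return validated variant table `data.frame`.
#' @export
variant_table <- function(info, mutant, total) {
  stopifnot(is.data.frame(info), nrow(info) == nrow(mutant),
            identical(dim(mutant), dim(total)))
  samples <- colnames(mutant)
  if (is.null(samples)) stop("count matrices must have sample ids as colnames")
  tab <- info[, VARIANT_INFO_COLS, drop = FALSE]
  for (s in samples) {
    tab[[paste0(s, ":mut")]] <- as.integer(mutant[, s])
    tab[[paste0(s, ":tot")]] <- as.integer(total[, s])
  }
  rownames(tab) <- NULL
  validate_variant_table(tab)
  tab
}

#' Validate a variant table
#'
#' Checks column layout, uniqueness of `mutation_id` and the per-cell
#' invariant `0 <= mutant_reads <= total_reads`.
#'
#' @param table candidate variant table.
#' @return the table, invisibly, if valid; otherwise an error naming the
#'   offending row and column.
#' @export
validate_variant_table <- function(table) {
  miss <- setdiff(VARIANT_INFO_COLS, colnames(table))
  if (length(miss)) stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  dup <- table$mutation_id[duplicated(table$mutation_id)]
  if (length(dup)) stop("duplicate mutation_id: ", paste(unique(dup), collapse = ", "))
  for (s in variant_samples(table)) {
    m <- table[[paste0(s, ":mut")]]
    t <- table[[paste0(s, ":tot")]]
    bad <- which(is.na(m) | is.na(t) | m < 0 | t < 0 | m > t)
    if (length(bad)) {
      stop(sprintf("invalid counts for mutation '%s', sample '%s' (mutant %s, total %s)",
                   table$mutation_id[bad[1]], s, m[bad[1]], t[bad[1]]))
    }
  }
  invisible(table)
}

#' Read / write a variant table (TSV)
#'
#' The on-disk format is UTF-8 tab-separated text with one header line; sample
#' columns are declared as `<sample_id>:mut` and `<sample_id>:tot`.
#'
#' @param path file path.
#' @return `read_variant_table`: a validated variant table, row order
#'   preserved.
#' @export
read_variant_table <- function(path) {
  # allele columns must never be type-guessed: a column of all "T" bases
  # would otherwise parse as logical
  chr_cols <- c(mutation_id = "character", contig = "character",
                ref_allele = "character", alt_allele = "character",
                gene = "character", mutation_class = "character")
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = chr_cols,
                           stringsAsFactors = FALSE)
  if ("gene" %in% colnames(tab)) tab$gene[is.na(tab$gene)] <- ""
  validate_variant_table(tab)
  tab
}

#' @rdname read_variant_table
#' @param table a validated variant table.
#' @export
write_variant_table <- function(table, path) {
  validate_variant_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sample sheet (TSV)
#'
#' Columns: `sample_id`, `treatment`, `replicate`, `generations` (elapsed
#' bacterial generations since the start of the experiment), and optionally the
#' mutS marker-allele frequencies `f_A41T` and `f_D1303` in \[0, 1\]. Marker
#' columns may be absent or empty.
#'
#' @param path file path.
#' @return a validated sample sheet `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  chr_cols <- c(sample_id = "character", treatment = "character",
                replicate = "character")
  sheet <- utils::read.delim(path, check.names = FALSE, colClasses = chr_cols,
                             stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "treatment", "replicate", "generations")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if (any(is.na(sheet$generations) | sheet$generations < 0)) {
    stop("generations must be nonnegative for every sample")
  }
  for (col in intersect(c("f_A41T", "f_D1303"), colnames(sheet))) {
    f <- sheet[[col]]
    bad <- which(!is.na(f) & (f < 0 | f > 1))
    if (length(bad)) {
      stop(sprintf("marker frequency %s = %s out of [0, 1] for sample '%s'",
                   col, f[bad[1]], sheet$sample_id[bad[1]]))
    }
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$replicate <- as.character(sheet$replicate)
  sheet
}

#' Marker columns present in a sample sheet
#'
#' @param sheet a sample sheet.
#' @return character vector among `c("f_A41T", "f_D1303")` that are present
#'   with at least one non-missing value.
#' @export
sheet_markers <- function(sheet) {
  cand <- intersect(c("f_A41T", "f_D1303"), colnames(sheet))
  cand[vapply(cand, function(col) any(!is.na(sheet[[col]])), logical(1))]
}

#' Allele-frequency matrix from read counts
#'
#' Builds the mutations x samples matrix of predicted allele frequencies
#' `mutant_reads / total_reads`. Zero-coverage cells (`total_reads = 0`) are
#' masked (`NA`).
#'
#' @param table a validated variant table.
#' @return numeric matrix with `mutation_id` rownames and sample colnames;
#'   `NA` marks masked cells.
#' @export
compute_frequencies <- function(table) {
  validate_variant_table(table)
  samples <- variant_samples(table)
  freq <- matrix(NA_real_, nrow(table), length(samples),
                 dimnames = list(table$mutation_id, samples))
  for (s in samples) {
    m <- table[[paste0(s, ":mut")]]
    t <- table[[paste0(s, ":tot")]]
    freq[, s] <- ifelse(t > 0, m / t, NA_real_)
  }
  freq
}

#' Summed mutation frequency of a sample
#'
#' The total summed frequency M_s of all (typically post-filtering) mutations
#' observed in a sample; masked cells contribute zero, so an all-masked column
#' sums to 0.
#'
#' @param freqs frequency matrix from [compute_frequencies()].
#' @param sample sample id(s); defaults to every column.
#' @return named numeric vector of M_s values.
#' @export
summed_frequency <- function(freqs, sample = colnames(freqs)) {
  unknown <- setdiff(sample, colnames(freqs))
  if (length(unknown)) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  ans <- colSums(freqs[, sample, drop = FALSE], na.rm = TRUE)
  if (nrow(freqs) == 0L) ans[] <- 0
  ans
}

#' Import RA evidence lines from a GenomeDiff file
#'
#' Minimal converter for the read-alignment (RA) evidence records of a
#' GenomeDiff file into one single-sample variant table. Only the fields this
#' pipeline consumes are read (position, ref/alt base, and the
#' `ref_cov`/`new_cov` read support); all other GenomeDiff semantics are out of
#' scope.
#'
#' @param path GenomeDiff file.
#' @param sample_id sample id for the resulting count column pair.
#' @return a variant table with one sample.
#' @export
read_genomediff_ra <- function(path, sample_id) {
  lines <- readLines(path, warn = FALSE)
  ra <- lines[startsWith(lines, "RA\t")]
  if (!length(ra)) stop("no RA evidence lines in ", path)
  parse_cov <- function(x) {
    # coverage fields look like "12/15" (top/bottom strand); sum the strands
    sum(as.numeric(strsplit(x, "/", fixed = TRUE)[[1]]))
  }
  rows <- lapply(ra, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    # RA <id> <parent> <seq_id> <pos> <insert_pos> <ref> <alt> [key=value ...]
    kv <- f[grepl("=", f, fixed = TRUE)]
    kv <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    ref_cov <- if ("ref_cov" %in% names(kv)) parse_cov(kv[["ref_cov"]]) else 0
    new_cov <- if ("new_cov" %in% names(kv)) parse_cov(kv[["new_cov"]]) else 0
    data.frame(contig = f[4], position = as.integer(f[5]),
               ref_allele = f[7], alt_allele = f[8],
               mut = new_cov, tot = ref_cov + new_cov,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  is_base <- rec$ref_allele %in% c("A", "C", "G", "T") &
    rec$alt_allele %in% c("A", "C", "G", "T")
  info <- data.frame(
    mutation_id = sprintf("%s_%d_%s>%s", rec$contig, rec$position,
                          rec$ref_allele, rec$alt_allele),
    contig = rec$contig, position = rec$position,
    ref_allele = rec$ref_allele, alt_allele = rec$alt_allele,
    gene = "", mutation_class = ifelse(is_base, "snv", "indel"),
    stringsAsFactors = FALSE)
  mutant <- matrix(as.integer(rec$mut), ncol = 1, dimnames = list(NULL, sample_id))
  total <- matrix(as.integer(rec$tot), ncol = 1, dimnames = list(NULL, sample_id))
  variant_table(info, mutant, total)
}
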