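#' Read a feature-by-sample abundance table with its sample metadata
#'
#' Tables are tab-separated, UTF-8, '.' decimal separator: a header row of
#' sample ids, first column feature ids. Empty cells and the token `NA`
#' are read as missing; missing values are rejected for count matrices.
#'
#' @param path Path to the abundance TSV.
#' @param kind Matrix kind, see [omics_matrix()].
#' @param meta_path Path to the sample metadata TSV with columns
#'   `sample_id`, `compartment`, `replicate`, `fraction`.
#' @return An [omics_matrix()].
#' @export
read_abundance_table <- function(path, kind = c("rna_counts", "protein_log2", "protein_ibaq"),
                                 meta_path) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("", "NA"), colClasses = "character",
                          quote = "")
  if (ncol(df) < 2) stop("abundance table needs a feature column and >= 1 sample", call. = FALSE)
  fid <- df[[1]]
  if (anyNA(fid) || anyDuplicated(fid)) {
    stop("feature ids must be present and unique", call. = FALSE)
  }
  sid <- colnames(df)[-1]
  if (anyDuplicated(sid)) stop("duplicate sample ids in header", call. = FALSE)
  values <- vapply(df[-1], function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (any(is.na(num) & !is.na(col))) {
      stop("non-numeric cell in abundance table", call. = FALSE)
    }
    num
  }, numeric(length(fid)))
  values <- matrix(values, nrow = length(fid), dimnames = list(fid, sid))
  meta <- read_sample_meta(meta_path)
  omics_matrix(values, kind, meta)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `compartment`, `replicate`,
#'   `fraction`.
#' @return Data frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character", quote = "")
  req <- c("sample_id", "compartment", "replicate", "fraction")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  meta
}

#' Write an abundance table (and optionally its metadata) to TSV
#'
#' Values are written with 15 significant digits so that a write/read
#' round trip preserves them to at least 12 significant digits; missing
#' cells are written as `NA`.
#'
#' @param x An [omics_matrix()].
#' @param path Output TSV path.
#' @param meta_path Optional path for the sample metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(x, path, meta_path = NULL) {
  v <- x$values
  body <- apply(v, 2, function(col) {
    out <- sprintf("%.15g", col)
    out[is.na(col)] <- "NA"
    out
  })
  body <- matrix(body, nrow = nrow(v))
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(meta_path)) write_tsv_plain(x$meta, meta_path)
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  fmt <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.15g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  })
  body <- do.call(paste, c(fmt, sep = "\t"))
  writeLines(c(paste(names(df), collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene...`.
#' Duplicate genes within a line are deduplicated.
#'
#' @param path Path to GMT file.
#' @return A `gene_set_collection`: named list of sets, each a list with
#'   `description` and `genes`.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    nm <- parts[[1]]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm, call. = FALSE)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set: ", nm, call. = FALSE)
    sets[[nm]] <- list(description = parts[[2]], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_set_collection` (see [read_gene_sets_gmt()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from FASTA
#'
#' The record id is the first whitespace-delimited token of the header;
#' wrapped sequence lines are joined and uppercased. A trailing `*`
#' (stop) is stripped; any other character outside the 20-letter
#' amino-acid alphabet is an error.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate FASTA record id", call. = FALSE)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  bad <- grepl(paste0("[^", paste(aa_alphabet, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("non-amino-acid character in sequence(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read the gene-level reference tables (half-lives and translatome labels)
#'
#' @param half_life_path TSV with columns `gene`, `half_life_hours`.
#' @param translatome_path TSV with columns `gene`, `translatome`
#'   (values `soma`, `neuropil`, `unbiased`).
#' @param fasta_path Optional protein FASTA (see [read_fasta()]).
#' @return List with `half_life` (named numeric, hours), `translatome`
#'   (named character) and `sequences` (named character or NULL).
#' @export
read_reference_tables <- function(half_life_path = NULL, translatome_path = NULL,
                                  fasta_path = NULL) {
  out <- list(half_life = NULL, translatome = NULL, sequences = NULL)
  if (!is.null(half_life_path)) {
    hl <- utils::read.delim(half_life_path, sep = "\t", check.names = FALSE, quote = "")
    if (!all(c("gene", "half_life_hours") %in% names(hl))) {
      stop("half-life table needs columns gene, half_life_hours", call. = FALSE)
    }
    v <- as.numeric(hl$half_life_hours)
    if (anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("half-lives must be finite and positive", call. = FALSE)
    }
    out$half_life <- stats::setNames(v, hl$gene)
  }
  if (!is.null(translatome_path)) {
    tr <- utils::read.delim(translatome_path, sep = "\t", check.names = FALSE, quote = "")
    if (!all(c("gene", "translatome") %in% names(tr))) {
      stop("translatome table needs columns gene, translatome", call. = FALSE)
    }
    if (!all(tr$translatome %in% c("soma", "neuropil", "unbiased"))) {
      stop("translatome labels must be soma/neuropil/unbiased", call. = FALSE)
    }
    out$translatome <- stats::setNames(as.character(tr$translatome), tr$gene)
  }
  if (!is.null(fasta_path)) out$sequences <- read_fasta(fasta_path)
  out
}

#' Write a bundle of pipeline products plus a run manifest
#'
#' Each data frame in `results` is written as a TSV named after its list
#' element; a JSON manifest records the configuration, seed, package
#' version and the files written. Outputs are deterministic: identical
#' inputs produce byte-identical files.
#'
#' @param results Named list of data frames (and/or `omics_matrix`
#'   objects, written via [write_abundance_table()]).
#' @param dir Output directory (created if needed).
#' @param config Run configuration to record in the manifest (any
#'   JSON-serializable list).
#' @param seed Integer seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_results_bundle <- function(results = list(), dir, config = list(), seed = NA_integer_) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (inherits(obj, "omics_matrix")) {
      write_abundance_table(obj, f)
    } else {
      write_tsv_plain(as.data.frame(obj), f)
    }
    files <- c(files, basename(f))
  }
  manifest <- list(
    package = "stratomics",
    version = as.character(utils::packageVersion("stratomics")),
    seed = seed,
    config = config,
    files = as.list(files)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mpath)
}
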