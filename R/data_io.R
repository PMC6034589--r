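# Readers/writers for the plain-text formats the pipeline touches:
# FASTA (proteomes, allele protein sequences), tab-delimited epitope/assay
# tables, allele catalogs, forbidden DQA1-DQB1 pair lists and disease
# association tables. All TSVs are UTF-8, tab-delimited, with '#' comment
# lines ignored.

#' The 20 standard amino-acid one-letter codes
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Natural amino-acid background frequencies
#'
#' Approximate residue frequencies of well-curated protein databases
#' (UniProtKB/Swiss-Prot scale), used as the default composition of the
#' synthetic generators so that k-mer occurrence counts show the dispersed,
#' heavy-tailed profile characteristic of real proteomes rather than the
#' degenerate all-rare profile a uniform composition produces at desk scale.
#' @export
AA_COMPOSITION <- c(A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039,
                    G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.097,
                    M = 0.024, N = 0.040, P = 0.047, Q = 0.039, R = 0.055,
                    S = 0.066, T = 0.053, V = 0.069, W = 0.011, Y = 0.029)
AA_COMPOSITION <- AA_COMPOSITION / sum(AA_COMPOSITION)

.AA_PATTERN <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Validate amino-acid sequences
#'
#' Sequences are normalised to uppercase; residues outside the 20-letter
#' alphabet plus `X` (unknown) are rejected, which catches corrupted inputs
#' early.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return the uppercased sequences, invisibly validated.
#' @keywords internal
validate_sequences <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- which(is.na(x) | !nzchar(x) | !grepl(.AA_PATTERN, x))
  if (length(bad)) {
    stop(sprintf("invalid %s at entry %d: %s", what, bad[1],
                 deparse(x[bad[1]])), call. = FALSE)
  }
  x
}

#' Read a FASTA file of amino-acid sequences
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] with located error
#' messages for malformed headers. Sequences are uppercased and whitespace
#' stripped; an empty file yields an empty table rather than an error.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id` and `sequence`, in file order.
#' @seealso [write_fasta()]
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "acdef"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("FASTA parse error at line %d: expected '>' header, got %s",
                 first, deparse(lines[first])), call. = FALSE)
  }
  empty_hdr <- which(trimws(lines) == ">")
  if (length(empty_hdr)) {
    stop(sprintf("FASTA parse error at line %d: empty record header",
                 empty_hdr[1]), call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- gsub("[[:space:]]", "", toupper(as.character(set)))
  data.frame(id = names(set), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write amino-acid sequences to FASTA
#'
#' @param records `data.frame` with columns `id` and `sequence` (or a named
#'   character vector of sequences).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", records$id)
  out[c(FALSE, TRUE)] <- records$sequence
  writeLines(out, path)
  invisible(path)
}

.read_tsv <- function(path, what = "table") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read an epitope/assay table
#'
#' Parses a tab-delimited export with one row per assay result. Mandatory
#' columns: `epitope_id`, `sequence`, `source_organism`. Optional:
#' `n_references` (defaults to 1), and the assay columns `allele`, `outcome`
#' (`positive`/`negative`, case-insensitive), `assay_class` (`mhc_binding` or
#' `t_cell`). Rows with duplicate (epitope, allele, class, outcome) are kept:
#' the downstream contingency analysis counts assays, not epitopes.
#'
#' @param path path to the TSV file.
#' @return a list with elements `epitopes` (`data.frame`: `id`, `sequence`,
#'   `source_organism`, `n_references`; one row per distinct epitope id) and
#'   `assays` (`data.frame`: `epitope_id`, `allele`, `outcome`,
#'   `assay_class`, or `NULL` when assay columns are absent).
#' @export
read_epitope_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("epitope_id", "sequence", "source_organism"), path)
  df$sequence <- toupper(df$sequence)
  bad <- which(!grepl(.AA_PATTERN, df$sequence))
  if (length(bad)) {
    stop(sprintf("row error in %s at data row %d: invalid sequence %s",
                 path, bad[1], deparse(df$sequence[bad[1]])), call. = FALSE)
  }
  if (is.null(df$n_references)) df$n_references <- 1L
  df$n_references <- as.integer(df$n_references)
  if (anyNA(df$n_references) || any(df$n_references < 0)) {
    stop("row error in ", path, ": n_references must be a non-negative integer",
         call. = FALSE)
  }
  epitopes <- df[!duplicated(df$epitope_id),
                 c("epitope_id", "sequence", "source_organism", "n_references")]
  names(epitopes)[1] <- "id"
  rownames(epitopes) <- NULL
  # one sequence per id
  seq_per_id <- tapply(df$sequence, df$epitope_id,
                       function(s) length(unique(s)))
  if (any(seq_per_id > 1)) {
    stop("row error in ", path, ": epitope id ",
         names(seq_per_id)[seq_per_id > 1][1],
         " maps to more than one sequence", call. = FALSE)
  }
  assays <- NULL
  if (all(c("allele", "outcome") %in% names(df))) {
    outcome <- tolower(trimws(df$outcome))
    has_assay <- nzchar(outcome) & !is.na(df$allele) & nzchar(df$allele)
    bad <- which(has_assay & !outcome %in% c("positive", "negative"))
    if (length(bad)) {
      stop(sprintf("row error in %s at data row %d: invalid outcome %s",
                   path, bad[1], deparse(df$outcome[bad[1]])), call. = FALSE)
    }
    if (any(has_assay)) {
      assay_class <- if (is.null(df$assay_class)) "mhc_binding" else df$assay_class
      assays <- data.frame(epitope_id = df$epitope_id[has_assay],
                           allele = df$allele[has_assay],
                           outcome = outcome[has_assay],
                           assay_class = tolower(assay_class)[has_assay],
                           stringsAsFactors = FALSE)
      bad_class <- which(!assays$assay_class %in% c("mhc_binding", "t_cell"))
      if (length(bad_class)) {
        stop(sprintf("row error in %s: invalid assay_class %s",
                     path, deparse(assays$assay_class[bad_class[1]])),
             call. = FALSE)
      }
      rownames(assays) <- NULL
    }
  }
  list(epitopes = epitopes, assays = assays)
}

#' Read a plain-text allele catalog
#'
#' One designation per line (e.g. `DQB1*03:02`), `#` comments and blank lines
#' ignored. Every designation must begin with the stated locus token.
#'
#' @param path path to the catalog file.
#' @param locus one of `"DQA1"`, `"DQB1"`, `"DRB1"`.
#' @return character vector of allele designations.
#' @export
read_allele_catalog <- function(path, locus = c("DQA1", "DQB1", "DRB1")) {
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- which(!startsWith(lines, locus))
  if (length(bad)) {
    stop(sprintf("allele catalog %s: designation %s does not begin with %s",
                 path, deparse(lines[bad[1]]), locus), call. = FALSE)
  }
  lines
}

#' Read a forbidden DQA1-DQB1 pair list
#'
#' @param path TSV with columns `dqa1`, `dqb1`, one forbidden alpha/beta
#'   combination per row.
#' @return `data.frame` with columns `dqa1`, `dqb1`.
#' @export
read_forbidden_pairs <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("dqa1", "dqb1"), path)
  df[c("dqa1", "dqb1")]
}

#' Read a disease-association table
#'
#' One row per association between an HLA allele (or an amino acid at a
#' position of an HLA chain) and a disease, with the odds ratio and p-value
#' of the association. Columns: `target_kind` (`allele` | `amino_acid`),
#' `allele`, `chain`, `position`, `residue`, `disease`, `odds_ratio`,
#' `p_value`; allele-level rows leave `position`/`residue` blank and
#' amino-acid rows leave `allele` blank.
#'
#' @param path path to the TSV file.
#' @return validated `data.frame` of associations.
#' @export
read_association_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("target_kind", "allele", "chain", "position",
                         "residue", "disease", "odds_ratio", "p_value"), path)
  if (!all(df$target_kind %in% c("allele", "amino_acid"))) {
    stop("association table ", path, ": target_kind must be allele or amino_acid",
         call. = FALSE)
  }
  if (!all(df$chain %in% c("DQA1", "DQB1", "DRB1"))) {
    stop("association table ", path, ": chain must be DQA1, DQB1 or DRB1",
         call. = FALSE)
  }
  df$odds_ratio <- as.numeric(df$odds_ratio)
  df$p_value <- as.numeric(df$p_value)
  if (any(!is.finite(df$odds_ratio)) || any(df$odds_ratio <= 0)) {
    stop("association table ", path, ": odds_ratio must be positive",
         call. = FALSE)
  }
  if (any(df$p_value < 0 | df$p_value > 1)) {
    stop("association table ", path, ": p_value must lie in [0,1]",
         call. = FALSE)
  }
  is_allele <- df$target_kind == "allele"
  allele_ok <- !is.na(df$allele) & nzchar(df$allele)
  aa_ok <- !is.na(df$position) & !is.na(df$residue) & nzchar(df$residue)
  if (any(is_allele & !allele_ok) || any(!is_allele & !aa_ok)) {
    stop("association table ", path,
         ": allele rows need allele, amino_acid rows need position+residue",
         call. = FALSE)
  }
  df$position <- suppressWarnings(as.integer(df$position))
  rownames(df) <- NULL
  df
}
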