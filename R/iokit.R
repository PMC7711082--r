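#' @title Expression-matrix I/O (TSV and GCT 1.2)
#'
#' @description \code{read_expression} reads a gene-by-sample matrix from a
#' tab-delimited file (first column gene id, header row of sample ids) or
#' a GCT 1.2 file (\code{#1.2} header, declared dimensions, gene id +
#' description columns). Readers validate rather than coerce: duplicate
#' ids, non-numeric cells, and dimension mismatches are errors with the
#' offending line or name.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"gct"}; \code{"auto"} picks GCT for
#'   a \code{.gct} extension.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
      stop("not a GCT 1.2 file (line 1 must be '#1.2'): ", path,
           call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2 || any(is.na(dims[1:2]))) {
      stop("GCT line 2 must declare '<n_genes>\\t<n_samples>'",
           call. = FALSE)
    }
    n_genes <- dims[1]; n_samples <- dims[2]
    header <- strsplit(lines[3], "\t")[[1]]
    sample_ids <- header[-(1:2)]
    if (length(sample_ids) != n_samples) {
      stop(sprintf(
        "GCT header declares %d sample columns but line 2 declares %d",
        length(sample_ids), n_samples), call. = FALSE)
    }
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != n_genes) {
      stop(sprintf(
        "GCT line 2 declares %d genes but file has %d data rows",
        n_genes, length(body)), call. = FALSE)
    }
    parsed <- strsplit(body, "\t")
    genes <- vapply(parsed, `[[`, "", 1)
    mat <- parse_numeric_rows(parsed, skip = 2, n_values = n_samples,
                              first_data_line = 4)
  } else {
    if (length(lines) < 2) stop("expression TSV needs a header and data rows",
                                call. = FALSE)
    sample_ids <- strsplit(lines[1], "\t")[[1]][-1]
    parsed <- strsplit(lines[-1], "\t")
    genes <- vapply(parsed, `[[`, "", 1)
    mat <- parse_numeric_rows(parsed, skip = 1, n_values = length(sample_ids),
                              first_data_line = 2)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(mat) <- list(genes, sample_ids)
  mat
}

parse_numeric_rows <- function(parsed, skip, n_values, first_data_line) {
  vals <- lapply(seq_along(parsed), function(i) {
    fields <- parsed[[i]][-seq_len(skip)]
    if (length(fields) != n_values) {
      stop(sprintf("line %d: expected %d values, found %d",
                   i + first_data_line - 1, n_values, length(fields)),
           call. = FALSE)
    }
    x <- suppressWarnings(as.numeric(fields))
    if (anyNA(x)) {
      stop(sprintf("line %d: non-numeric cell '%s'",
                   i + first_data_line - 1, fields[which(is.na(x))[1]]),
           call. = FALSE)
    }
    x
  })
  do.call(rbind, vals)
}

#' Write an expression matrix
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @param format \code{"tsv"} (header row of sample ids, first column
#'   \code{gene}) or \code{"gct"} (GCT 1.2 with an empty description
#'   column).
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  check_expression_matrix(expr)
  rows <- apply(expr, 1, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  if (format == "gct") {
    lines <- c("#1.2",
               paste(nrow(expr), ncol(expr), sep = "\t"),
               paste(c("NAME", "Description", colnames(expr)),
                     collapse = "\t"),
               paste(rownames(expr), "na", rows, sep = "\t"))
  } else {
    lines <- c(paste(c("gene", colnames(expr)), collapse = "\t"),
               paste(rownames(expr), rows, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a clinical annotation table
#'
#' Tab-delimited, one row per sample, with required columns
#' \code{sample_id} and \code{fusion_status} (values \code{positive},
#' \code{negative}, \code{erg_other}); optional \code{age},
#' \code{gleason}, \code{time}, \code{event}; any further numeric columns
#' are carried through as covariates. Missing values are written as
#' \code{NA}.
#'
#' @param path file path.
#' @return \code{read_clinical}: a validated data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  check_clinical(df, require_survival = FALSE)
}

#' @rdname read_clinical
#' @param clinical a clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a signature file
#'
#' Two-column tab-delimited \code{gene<TAB>weight}. No header by default;
#' weights are validated on read (in [-1,1], nonzero) and printed with 6
#' decimals on write.
#'
#' @param path file path.
#' @param header whether the file has / should get a header row.
#' @return \code{read_signature}: a \code{fusion_signature}.
#' @export
read_signature <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty signature", call. = FALSE)
  parts <- strsplit(lines, "\t")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 2) {
      stop(sprintf("signature row %d: expected 'gene<TAB>weight'", i),
           call. = FALSE)
    }
  }
  genes <- vapply(parts, `[[`, "", 1)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  bad <- which(is.na(w) | w == 0 | abs(w) > 1)
  if (length(bad)) {
    stop(sprintf(
      "signature row %d: weight must be a nonzero number in [-1, 1]",
      bad[1]), call. = FALSE)
  }
  new_signature(genes, w, id = basename(path))
}

#' @rdname read_signature
#' @param signature a \code{fusion_signature}.
#' @export
write_signature <- function(signature, path, header = FALSE) {
  validate_signature(signature)
  lines <- sprintf("%s\t%.6f", signature$gene, signature$weight)
  if (header) lines <- c("gene\tweight", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write per-sample scores
#'
#' Tab-delimited \code{sample_id<TAB>score} with 6 decimals, plus a JSON
#' sidecar (\code{<path>.json}) recording the scoring metadata (seed,
#' permutation count, statistic variant, dropped genes).
#'
#' @param scores named score vector from [score_samples()].
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  writeLines(c("sample_id\tscore",
               sprintf("%s\t%.6f", names(scores), as.numeric(scores))),
             path)
  meta <- list(
    n_permutations = attr(scores, "n_permutations"),
    seed = attr(scores, "seed"),
    signature_id = attr(scores, "signature_id"),
    statistic = attr(scores, "statistic"),
    dropped_genes = as.list(attr(scores, "dropped_genes"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @return \code{read_scores}: a named numeric vector.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$score), df$sample_id)
}

#' Serialize an evaluation report or simulation truth to JSON
#'
#' @param x an \code{evaluation_report} or the \code{truth} component of
#'   [simulate_cohort()].
#' @param path output path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass_recursive(x), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
    attributes(x) <- list(names = names(x))
    x
  } else if (!is.null(attributes(x)) && !is.factor(x) &&
             !is.data.frame(x)) {
    attrs <- attributes(x)
    keep <- intersect(names(attrs), c("names", "dim", "dimnames"))
    attributes(x) <- attrs[keep]
    x
  } else {
    x
  }
}

# --- shared validation -------------------------------------------------

check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  invisible(expr)
}

check_clinical <- function(clinical, require_survival = FALSE) {
  if (!is.data.frame(clinical)) {
    stop("clinical must be a data.frame", call. = FALSE)
  }
  req <- c("sample_id", "fusion_status")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(clinical$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  ok_status <- clinical$fusion_status %in%
    c("positive", "negative", "erg_other")
  if (!all(ok_status)) {
    stop("fusion_status must be one of positive/negative/erg_other; bad: ",
         paste(unique(clinical$fusion_status[!ok_status]), collapse = ", "),
         call. = FALSE)
  }
  if ("event" %in% names(clinical)) {
    ev <- clinical$event[!is.na(clinical$event)]
    if (!all(ev %in% c(0, 1))) {
      stop("event must be 0 or 1", call. = FALSE)
    }
  }
  if ("time" %in% names(clinical)) {
    tm <- clinical$time[!is.na(clinical$time)]
    if (any(tm < 0)) stop("time must be >= 0", call. = FALSE)
  }
  if (require_survival && !all(c("time", "event") %in% names(clinical))) {
    stop("clinical table needs 'time' and 'event' columns", call. = FALSE)
  }
  clinical
}
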