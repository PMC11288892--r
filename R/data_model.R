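#' Peptide-level LiP-MS dataset
#'
#' Container for replicate peptide intensities over a temperature gradient.
#' `records` holds one row per peptide with protein coordinates (1-based,
#' inclusive) and tryptic type; `intensities` is a long table of raw,
#' non-negative intensities keyed by (peptide, condition, replicate,
#' temperature).  Zero intensities are treated as missing (DIA zeros mean
#' not-quantified, and downstream operations work on a log scale).
#'
#' @param records data.frame with columns `protein_id`, `peptide_id`,
#'   `start`, `end`, `tryptic_type` ("FT" or "HT") and optionally
#'   `proteotypic` (logical, default `TRUE`).
#' @param intensities data.frame with columns `peptide_id`, `condition`,
#'   `replicate`, `temperature`, `intensity`.
#' @param grid temperature grid (degrees C); defaults to [lip_grid()].
#' @return an object of class `peptide_dataset`.
#' @export
peptide_dataset <- function(records, intensities, grid = lip_grid()) {
  check_grid(grid)
  req_rec <- c("protein_id", "peptide_id", "start", "end", "tryptic_type")
  if (!all(req_rec %in% names(records))) {
    stop("records must have columns: ", paste(req_rec, collapse = ", "))
  }
  if (is.null(records$proteotypic)) records$proteotypic <- TRUE
  req_int <- c("peptide_id", "condition", "replicate", "temperature", "intensity")
  if (!all(req_int %in% names(intensities))) {
    stop("intensities must have columns: ", paste(req_int, collapse = ", "))
  }
  bad <- records$start < 1L | records$end < records$start
  if (any(bad)) stop("invalid peptide coordinates (need 1 <= start <= end)")
  if (!all(records$tryptic_type %in% c("FT", "HT"))) {
    stop("tryptic_type must be 'FT' or 'HT'")
  }
  if (anyDuplicated(records$peptide_id)) stop("duplicate peptide_id in records")
  key <- paste(intensities$peptide_id, intensities$condition,
               intensities$replicate, intensities$temperature, sep = "\r")
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (peptide, condition, replicate, temperature) rows")
  }
  x <- intensities$intensity
  x[!is.finite(x) | x <= 0] <- NA_real_  # zero / non-numeric => missing
  if (any(x < 0, na.rm = TRUE)) stop("negative intensities")
  intensities$intensity <- x
  structure(
    list(records = as.data.frame(records),
         intensities = as.data.frame(intensities),
         grid = as.numeric(grid),
         conditions = sort(unique(as.character(intensities$condition)))),
    class = "peptide_dataset")
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat("peptide_dataset:", nrow(x$records), "peptides,",
      length(unique(x$records$protein_id)), "proteins\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  gradient:", length(x$grid), "temperatures,",
      min(x$grid), "-", max(x$grid), "degC\n")
  cat("  intensities:", nrow(x$intensities), "rows (",
      sum(is.na(x$intensities$intensity)), "missing )\n")
  invisible(x)
}

#' @export
summary.peptide_dataset <- function(object, ...) {
  with(object, {
    cat("Peptides by tryptic type:\n")
    print(table(records$tryptic_type))
    cat("Observations per condition:\n")
    print(table(intensities$condition, useNA = "no"))
  })
  invisible(object)
}

#' Read / write a long-format peptide quantification table
#'
#' The native format is a TSV with columns `protein_id`, `peptide`, `start`,
#' `end`, `tryptic_type`, `condition`, `replicate`, `temperature_C`,
#' `intensity`.  `schema` renames arbitrary export headers onto these, e.g.
#' `c(peptide = "EG.PrecursorId")`.  Non-numeric intensity fields become
#' missing values; duplicated keys are an error.
#'
#' @param path file path (TSV, or CSV if the name ends in `.csv`).
#' @param schema named character vector mapping required column names to the
#'   file's column names.
#' @param grid temperature grid; defaults to the temperatures found in the
#'   file if they are >= 4, else [lip_grid()].
#' @return [read_peptide_table()]: a [peptide_dataset()].
#' @export
read_peptide_table <- function(path, schema = NULL, grid = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  req <- c("protein_id", "peptide", "start", "end", "tryptic_type",
           "condition", "replicate", "temperature_C", "intensity")
  if (!is.null(schema)) {
    for (nm in names(schema)) {
      if (!schema[[nm]] %in% names(df)) {
        stop("schema error: mapped column '", schema[[nm]], "' not in file")
      }
      names(df)[names(df) == schema[[nm]]] <- nm
    }
  }
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("schema error: missing required column(s): ",
                         paste(miss, collapse = ", "))
  temperature <- as.numeric(df$temperature_C)
  if (anyNA(temperature)) stop("temperatures must be numeric")
  intensity <- suppressWarnings(as.numeric(df$intensity))  # non-numeric -> NA
  records <- unique(data.frame(
    protein_id = df$protein_id, peptide_id = df$peptide,
    start = as.integer(df$start), end = as.integer(df$end),
    tryptic_type = df$tryptic_type, stringsAsFactors = FALSE))
  intens <- data.frame(
    peptide_id = df$peptide, condition = df$condition,
    replicate = as.integer(df$replicate), temperature = temperature,
    intensity = intensity, stringsAsFactors = FALSE)
  if (is.null(grid)) {
    tt <- sort(unique(temperature))
    grid <- if (length(tt) >= 4) tt else lip_grid()
  }
  peptide_dataset(records, intens, grid = grid)
}

#' @param dataset a [peptide_dataset()].
#' @rdname read_peptide_table
#' @export
write_peptide_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "peptide_dataset"))
  m <- match(dataset$intensities$peptide_id, dataset$records$peptide_id)
  out <- data.frame(
    protein_id = dataset$records$protein_id[m],
    peptide = dataset$intensities$peptide_id,
    start = dataset$records$start[m],
    end = dataset$records$end[m],
    tryptic_type = dataset$records$tryptic_type[m],
    condition = dataset$intensities$condition,
    replicate = dataset$intensities$replicate,
    temperature_C = dataset$intensities$temperature,
    intensity = dataset$intensities$intensity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Protein solubility (TPP) dataset
#'
#' Soluble-fraction protein abundance per (condition, replicate,
#' temperature), scaled so that the value at the lowest gradient temperature
#' (37 degrees C) is exactly 1 for every (protein, condition, replicate)
#' series.
#'
#' @param abundances data.frame with columns `protein_id`, `condition`,
#'   `replicate`, `temperature`, `abundance` (raw or already scaled).
#' @param rescale rescale each series to its 37 degC value (default `TRUE`).
#' @param grid temperature grid.
#' @return object of class `solubility_dataset`.
#' @export
protein_solubility_dataset <- function(abundances, rescale = TRUE,
                                       grid = lip_grid()) {
  check_grid(grid)
  req <- c("protein_id", "condition", "replicate", "temperature", "abundance")
  if (!all(req %in% names(abundances))) {
    stop("abundances must have columns: ", paste(req, collapse = ", "))
  }
  ab <- as.data.frame(abundances)
  if (any(ab$abundance < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  if (rescale) {
    key <- paste(ab$protein_id, ab$condition, ab$replicate, sep = "\r")
    t0 <- min(grid)
    ref <- ab$abundance[ab$temperature == t0]
    names(ref) <- key[ab$temperature == t0]
    if (anyDuplicated(names(ref))) stop("duplicate reference rows at ", t0, " degC")
    r <- ref[key]
    if (anyNA(r) || any(r <= 0)) stop("every series needs a positive value at ", t0, " degC")
    ab$abundance <- ab$abundance / r
  }
  structure(list(abundances = ab, grid = as.numeric(grid),
                 conditions = sort(unique(as.character(ab$condition)))),
            class = "solubility_dataset")
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat("solubility_dataset:", length(unique(x$abundances$protein_id)),
      "proteins;", "conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Read a domain annotation table
#'
#' TSV with columns `protein_id`, `domain_id`, `start`, `end` (1-based
#' inclusive residue coordinates).  Overlapping domains within one protein
#' are rejected.
#'
#' @param path file path.
#' @return data.frame of validated domain ranges.
#' @export
read_domain_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_domains(df)
}

validate_domains <- function(df) {
  req <- c("protein_id", "domain_id", "start", "end")
  if (!all(req %in% names(df))) {
    stop("domain table must have columns: ", paste(req, collapse = ", "))
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1L | df$end < df$start)) stop("invalid domain coordinates")
  for (p in unique(df$protein_id)) {
    d <- df[df$protein_id == p, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("overlapping domains for protein ", p)
    }
  }
  df
}

#' Match half-tryptic peptides to containing fully tryptic peptides
#'
#' A half-tryptic (HT) peptide is paired with a fully tryptic (FT) peptide
#' of the same protein when its borders lie within the FT peptide's borders
#' (containment, borders may coincide).  One HT peptide may pair with
#' several FT peptides.
#'
#' @param dataset a [peptide_dataset()].
#' @return data.frame with columns `ht`, `ft`, `protein_id` (possibly empty).
#' @export
match_ht_to_ft <- function(dataset) {
  rec <- dataset$records
  ht <- rec[rec$tryptic_type == "HT", , drop = FALSE]
  ft <- rec[rec$tryptic_type == "FT", , drop = FALSE]
  out <- list()
  for (p in intersect(unique(ht$protein_id), unique(ft$protein_id))) {
    h <- ht[ht$protein_id == p, , drop = FALSE]
    f <- ft[ft$protein_id == p, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      hit <- f$start <= h$start[i] & h$end[i] <= f$end
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          ht = h$peptide_id[i], ft = f$peptide_id[hit], protein_id = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ht = character(), ft = character(),
                      protein_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Pearson correlation of matched HT/FT peptide intensities
#'
#' For each (HT, FT) pair the Pearson correlation of raw intensities over
#' the shared (condition, replicate, temperature) observations.  Pairs with
#' fewer than 3 shared finite observations are skipped with a warning.
#'
#' @param pairs output of [match_ht_to_ft()].
#' @param dataset the [peptide_dataset()].
#' @return `pairs` with an added numeric column `r` (skipped pairs dropped).
#' @export
ht_ft_correlation <- function(pairs, dataset) {
  ints <- dataset$intensities
  key <- function(d) paste(d$condition, d$replicate, d$temperature, sep = "\r")
  by_pep <- split(ints, ints$peptide_id)
  r <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- by_pep[[pairs$ht[i]]]; b <- by_pep[[pairs$ft[i]]]
    if (is.null(a) || is.null(b)) next
    m <- match(key(a), key(b))
    ok <- !is.na(m) & is.finite(a$intensity) & is.finite(b$intensity[m])
    if (sum(ok) < 3L) next
    r[i] <- stats::cor(a$intensity[ok], b$intensity[m][ok])
  }
  if (anyNA(r)) {
    warning(sum(is.na(r)), " pair(s) skipped (<3 shared observations)")
  }
  cbind(pairs, r = r)[!is.na(r), , drop = FALSE]
}
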