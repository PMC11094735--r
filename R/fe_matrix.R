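#' Adsorption free-energy matrix
#'
#' Container for a complete biomolecule x nanomaterial matrix of adsorption
#' free energies (kJ/mol), optionally with elementwise lower/upper
#' uncertainty bounds. Rows are molecules, columns are materials; both axes
#' carry unique character ids.
#'
#' @param values numeric matrix (kJ/mol) with unique rownames (molecule ids)
#'   and colnames (material ids); all entries must be finite.
#' @param lower,upper optional numeric matrices of the same shape giving
#'   elementwise bounds with `lower <= values <= upper`.
#' @return An object of class `fe_matrix`: a list with elements `values`,
#'   `lower`, `upper`, `molecule_ids`, `material_ids`.
#' @examples
#' m <- fe_matrix(matrix(c(-1, -2, 0, 0.5), 2, 2,
#'                dimnames = list(c("X", "Y"), c("A", "B"))))
#' m$molecule_ids
#' @export
fe_matrix <- function(values, lower = NULL, upper = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  mol <- rownames(values)
  mat <- colnames(values)
  if (is.null(mol) || is.null(mat))
    stop("`values` must carry molecule rownames and material colnames",
         call. = FALSE)
  dup <- mol[duplicated(mol)]
  if (length(dup))
    stop("duplicate molecule id: ", dup[1L], call. = FALSE)
  dup <- mat[duplicated(mat)]
  if (length(dup))
    stop("duplicate material id: ", dup[1L], call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite free energy for molecule '", mol[bad[1L, 1L]],
         "', material '", mat[bad[1L, 2L]], "'", call. = FALSE)
  for (nm in c("lower", "upper")) {
    b <- get(nm)
    if (!is.null(b)) {
      if (!is.matrix(b) || !identical(dim(b), dim(values)))
        stop("`", nm, "` must match the shape of `values`", call. = FALSE)
      if (any(!is.finite(b)))
        stop("non-finite entries in `", nm, "`", call. = FALSE)
      dimnames(b) <- dimnames(values)
      assign(nm, b)
    }
  }
  if (!is.null(lower) && any(lower > values + 1e-12))
    stop("lower bound exceeds value", call. = FALSE)
  if (!is.null(upper) && any(upper < values - 1e-12))
    stop("upper bound below value", call. = FALSE)
  structure(list(values = values, lower = lower, upper = upper,
                 molecule_ids = mol, material_ids = mat),
            class = "fe_matrix")
}

#' @export
print.fe_matrix <- function(x, ...) {
  cat(sprintf("<fe_matrix> %d molecules x %d materials (kJ/mol)%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$lower)) ", with bounds" else ""))
  cat("molecules:", paste(utils::head(x$molecule_ids, 6), collapse = ", "),
      if (length(x$molecule_ids) > 6) "..." else "", "\n")
  cat("materials:", paste(utils::head(x$material_ids, 6), collapse = ", "),
      if (length(x$material_ids) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.fe_matrix <- function(x) dim(x$values)

.fe_delim <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("tsv", "tab", "txt")) "tsv" else "csv"
  }
  if (dialect == "csv") "," else "\t"
}

.read_delim_matrix <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  rn <- trimws(df[[1L]])
  cn <- colnames(df)[-1L]
  if (anyDuplicated(rn))
    stop("duplicate row label: ", rn[duplicated(rn)][1L], call. = FALSE)
  if (anyDuplicated(cn))
    stop("duplicate column label: ", cn[duplicated(cn)][1L], call. = FALSE)
  df <- df[-1L]
  vals <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(rn, cn))
  for (j in seq_along(cn)) {
    raw <- trimws(df[[j]])
    if (any(raw == "" | is.na(raw))) {
      i <- which(raw == "" | is.na(raw))[1L]
      stop("missing value at row '", rn[i], "', column '", cn[j],
           "' (the pipeline requires a complete matrix)", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      stop("non-numeric value '", raw[i], "' at row '", rn[i],
           "', column '", cn[j], "'", call. = FALSE)
    }
    vals[, j] <- num
  }
  vals
}

.bound_path <- function(path, suffix) {
  ext <- tools::file_ext(path)
  if (nzchar(ext))
    sub(paste0("\\.", ext, "$"), paste0(suffix, ".", ext), path)
  else paste0(path, suffix)
}

#' Read an adsorption free-energy matrix from delimited text
#'
#' Reads a header row of material ids and a first column of molecule ids
#' (or the transpose, see `orientation`). Companion files with `_min` /
#' `_max` inserted before the extension are picked up as lower/upper
#' uncertainty bounds when present.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect `"auto"` (from extension; `.tsv`/`.tab`/`.txt` are
#'   tab-separated, anything else comma), `"csv"` or `"tsv"`. Decimal
#'   separator is always `"."`.
#' @param orientation `"molecules"` if rows are molecules (default),
#'   `"materials"` if rows are materials (the matrix is transposed on read).
#' @param bounds `"auto"` to load `_min`/`_max` companions when both exist,
#'   `"none"` to ignore them.
#' @return An [fe_matrix()], always normalized to molecules-as-rows.
#' @export
read_fe_matrix <- function(path, dialect = c("auto", "csv", "tsv"),
                           orientation = c("molecules", "materials"),
                           bounds = c("auto", "none")) {
  orientation <- match.arg(orientation)
  bounds <- match.arg(bounds)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  sep <- .fe_delim(path, match.arg(dialect))
  vals <- .read_delim_matrix(path, sep)
  lo <- hi <- NULL
  if (bounds == "auto") {
    pmin <- .bound_path(path, "_min")
    pmax <- .bound_path(path, "_max")
    if (file.exists(pmin) && file.exists(pmax)) {
      lo <- .read_delim_matrix(pmin, sep)
      hi <- .read_delim_matrix(pmax, sep)
    }
  }
  if (orientation == "materials") {
    vals <- t(vals)
    if (!is.null(lo)) lo <- t(lo)
    if (!is.null(hi)) hi <- t(hi)
  }
  fe_matrix(vals, lower = lo, upper = hi)
}

#' Write an adsorption free-energy matrix to delimited text
#'
#' Numbers are written with 17 significant digits so that
#' `read_fe_matrix(write_fe_matrix(m, p))` reproduces `m` exactly. Bounds,
#' when present, go to `_min`/`_max` companion files.
#'
#' @param m an [fe_matrix()].
#' @param path output path.
#' @param dialect see [read_fe_matrix()].
#' @return `path`, invisibly.
#' @export
write_fe_matrix <- function(m, path, dialect = c("auto", "csv", "tsv")) {
  stopifnot(inherits(m, "fe_matrix"))
  sep <- .fe_delim(path, match.arg(dialect))
  .write_one <- function(vals, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste(c("id", colnames(vals)), collapse = sep), con)
    for (i in seq_len(nrow(vals)))
      writeLines(paste(c(rownames(vals)[i],
                         sprintf("%.17g", vals[i, ])), collapse = sep), con)
  }
  .write_one(m$values, path)
  if (!is.null(m$lower) && !is.null(m$upper)) {
    .write_one(m$lower, .bound_path(path, "_min"))
    .write_one(m$upper, .bound_path(path, "_max"))
  }
  invisible(path)
}

#' Subset an fe_matrix by molecule and/or material ids
#'
#' @param m an [fe_matrix()].
#' @param molecules,materials character vectors of ids to keep (default all).
#' @return An [fe_matrix()] restricted to the requested ids, in the
#'   requested order.
#' @export
fe_subset <- function(m, molecules = m$molecule_ids,
                      materials = m$material_ids) {
  stopifnot(inherits(m, "fe_matrix"))
  miss <- setdiff(molecules, m$molecule_ids)
  if (length(miss)) stop("unknown molecule id: ", miss[1L], call. = FALSE)
  miss <- setdiff(materials, m$material_ids)
  if (length(miss)) stop("unknown material id: ", miss[1L], call. = FALSE)
  sub <- function(x) if (is.null(x)) NULL else
    x[molecules, materials, drop = FALSE]
  fe_matrix(sub(m$values), lower = sub(m$lower), upper = sub(m$upper))
}

#' Path to a locally provided reference adsorption matrix
#'
#' The deposited 32 x 33 amino-acid/lipid-fragment adsorption free-energy
#' dataset is not distributed with this package. To run the reference
#' analyses, download it from the public archive and place the matrix (CSV,
#' molecules as rows) at `inst/extdata/reference/dg_matrix.csv` before
#' installing, or point `options(bionanofp.reference_matrix = "...")` at a
#' copy.
#'
#' @return The path where the reference matrix is expected. The file may or
#'   may not exist; callers should check with `file.exists()`.
#' @export
reference_matrix_path <- function() {
  opt <- getOption("bionanofp.reference_matrix", NULL)
  if (!is.null(opt)) return(opt)
  system.file("extdata", "reference", "dg_matrix.csv",
              package = "bionanofp") %||%
    file.path("inst", "extdata", "reference", "dg_matrix.csv")
}

`%||%` <- function(a, b) if (is.null(a) || identical(a, "")) b else a
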