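#' Read a design matrix and response from delimited text
#'
#' Reads a numeric design matrix and a single-column response from CSV or
#' TSV files (the delimiter is inferred from the extension, with comma as
#' the fallback), validates that every cell is numeric, that the files have
#' consistent row counts, and that \eqn{n > 2d} as the two-step procedure
#' requires.
#'
#' @param x_path path to the design matrix file.
#' @param y_path path to the response file (one column).
#' @param has_header logical; take column names from the first row of the
#'   design file (default \code{TRUE}); otherwise columns are named
#'   \code{X1..Xd}.
#' @return List with \code{x} (numeric matrix), \code{y} (numeric vector)
#'   and \code{names} (column names).
#' @export
read_gts_dataset <- function(x_path, y_path, has_header = TRUE) {
  xdf <- read_delim_auto(x_path, has_header)
  ydf <- read_delim_auto(y_path, has_header)
  if (ncol(ydf) != 1) {
    stop("response file must have exactly one column", call. = FALSE)
  }
  if (!all(vapply(xdf, is.numeric, logical(1))) || !is.numeric(ydf[[1]])) {
    stop("non-numeric cells in input files", call. = FALSE)
  }
  x <- as.matrix(xdf)
  y <- ydf[[1]]
  if (nrow(x) != length(y)) {
    stop("design and response have inconsistent row counts (",
         nrow(x), " vs ", length(y), ")", call. = FALSE)
  }
  if (nrow(x) <= 2 * ncol(x)) {
    stop("the method requires n > 2d, got n = ", nrow(x), ", d = ",
         ncol(x), call. = FALSE)
  }
  nms <- if (has_header) colnames(x) else paste0("X", seq_len(ncol(x)))
  colnames(x) <- nms
  list(x = x, y = y, names = nms)
}

read_delim_auto <- function(path, has_header) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  out <- utils::read.table(path, header = has_header, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("empty file: ", path, call. = FALSE)
  out
}

#' Run the full pipeline from files and write a decisions table
#'
#' Thin wrapper over \code{\link{gts}} for file-based use: reads the
#' dataset, runs the configured analysis, and (optionally) writes the
#' per-coefficient decision table as TSV with a provenance header recording
#' the configuration and seed, sufficient to reproduce the run exactly.
#'
#' @param x_path,y_path,has_header passed to \code{\link{read_gts_dataset}}.
#' @param family,alpha,method,regen,delta_c,lam,lambda0,seed,standardize
#'   passed to \code{\link{gts}}.
#' @param out optional output TSV path; when supplied the decision table is
#'   written via \code{\link{write_gts_decisions}}.
#' @return The \code{"gts"} object, invisibly when \code{out} is given.
#' @export
run_gts_pipeline <- function(x_path, y_path, family = "binomial",
                             alpha = 0.1, method = "gts",
                             regen = "row_permutation", delta_c = 1.1,
                             lam = NULL, lambda0 = 0.5, seed = 1,
                             standardize = FALSE, has_header = TRUE,
                             out = NULL) {
  dat <- read_gts_dataset(x_path, y_path, has_header)
  res <- gts(dat$x, dat$y, family = family, alpha = alpha, method = method,
             regen = regen, delta_c = delta_c, lam = lam, lambda0 = lambda0,
             seed = seed, standardize = standardize)
  if (!is.null(out)) {
    write_gts_decisions(res, out)
    return(invisible(res))
  }
  res
}

#' Write (and read back) the per-coefficient decision table
#'
#' The TSV has one row per coefficient with columns index, name, beta1,
#' beta2, se1, se2, p1, p2, ptilde, screened, rejected; \code{#}-prefixed
#' header lines record the package version and the run configuration
#' (alpha, method, strategy, delta_c, lambda, seed, pi0_hat).
#'
#' @param object a \code{"gts"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gts_decisions <- function(object, path) {
  stopifnot(inherits(object, "gts"))
  tab <- summary(object)
  h <- attr(tab, "header")
  hdr <- c(
    paste0("# gtsfdr ", as.character(utils::packageVersion("gtsfdr"))),
    paste0("# alpha=", h$alpha, " method=", h$method,
           " strategy=", h$strategy, " delta_c=", h$delta_c,
           if (!is.null(h$lam)) paste0(" lambda=", h$lam),
           if (!is.null(h$seed)) paste0(" seed=", h$seed),
           if (!is.null(h$pi0_hat))
             paste0(" pi0_hat=", format(h$pi0_hat, digits = 8)))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gts_decisions
#' @export
read_gts_decisions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
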