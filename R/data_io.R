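# Data containers, file I/O and run configuration.

#' Construct a response time / accuracy dataset
#'
#' Bundles an N x K binary accuracy matrix \code{X} and an N x K positive
#' response-time matrix \code{T} (seconds) with person and item labels, and
#' validates the joint invariants: identical shapes, strictly positive
#' times, 0/1 accuracies, no missing cells.
#'
#' @param X numeric matrix of 0/1 accuracies, persons in rows.
#' @param T numeric matrix of response times in seconds, same shape.
#' @param person_ids optional length-N character labels.
#' @param item_ids optional length-K character labels.
#' @return an object of class \code{rtc_dataset} with elements \code{X},
#'   \code{T}, \code{person_ids}, \code{item_ids}, \code{N}, \code{K}.
#' @export
rtc_dataset <- function(X, T, person_ids = NULL, item_ids = NULL) {
  X <- as.matrix(X); T <- as.matrix(T)
  if (!identical(dim(X), dim(T))) {
    stop(sprintf("shape mismatch: X is %dx%d but T is %dx%d",
                 nrow(X), ncol(X), nrow(T), ncol(T)), call. = FALSE)
  }
  if (anyNA(X) || anyNA(T)) stop("missing cells are not supported", call. = FALSE)
  bad <- which(!(X == 0 | X == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary accuracy value %g at (person %d, item %d)",
                 X[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  bad <- which(T <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive response time %g at (person %d, item %d)",
                 T[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  if (is.null(person_ids)) person_ids <- paste0("p", seq_len(nrow(X)))
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(X)))
  stopifnot(length(person_ids) == nrow(X), length(item_ids) == ncol(X))
  structure(list(X = unname(X), T = unname(T),
                 person_ids = as.character(person_ids),
                 item_ids = as.character(item_ids),
                 N = nrow(X), K = ncol(X)),
            class = "rtc_dataset")
}

#' @export
print.rtc_dataset <- function(x, ...) {
  cat(sprintf("<rtc_dataset> %d persons x %d items; mean accuracy %.3f; median RT %.2fs\n",
              x$N, x$K, mean(x$X), stats::median(x$T)))
  invisible(x)
}

#' Read a dataset from a pair of delimited text files
#'
#' Both files are comma-separated with a header row of item ids and one row
#' per person whose first column is the person id.  Row and column order are
#' preserved.
#'
#' @param x_path path to the accuracy CSV.
#' @param t_path path to the response-time CSV.
#' @return validated \code{\link{rtc_dataset}}.
#' @export
read_dataset <- function(x_path, t_path) {
  xd <- read.csv(x_path, check.names = FALSE)
  td <- read.csv(t_path, check.names = FALSE)
  X <- as.matrix(xd[, -1, drop = FALSE])
  T <- as.matrix(td[, -1, drop = FALSE])
  if (!identical(dim(X), dim(T))) {
    stop(sprintf("shape mismatch between files: X is %dx%d, T is %dx%d",
                 nrow(X), ncol(X), nrow(T), ncol(T)), call. = FALSE)
  }
  rtc_dataset(X, T, person_ids = xd[[1]], item_ids = colnames(xd)[-1])
}

#' Write a dataset to a pair of delimited text files
#'
#' Inverse of \code{\link{read_dataset}}: comma-separated, header row of item
#' ids, first column holds person ids.
#'
#' @param data an \code{\link{rtc_dataset}}.
#' @param x_path,t_path output paths.
#' @return invisibly, \code{data}.
#' @export
write_dataset <- function(data, x_path, t_path) {
  stopifnot(inherits(data, "rtc_dataset"))
  dfx <- data.frame(person = data$person_ids, data$X, check.names = FALSE)
  dft <- data.frame(person = data$person_ids, data$T, check.names = FALSE)
  colnames(dfx) <- colnames(dft) <- c("person", data$item_ids)
  write.csv(dfx, x_path, row.names = FALSE, quote = FALSE)
  write.csv(dft, t_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Default analysis configuration
#'
#' Defaults reproduce the reference analysis settings: 10,000 Gibbs
#' iterations with 5,000 burn-in; multiple-category thresholds
#' (-1.5, -0.5, 0.5, 1.5) with the middle category as baseline; focal points
#' -2 to 2 in steps of 0.5; bandwidth factor h = 1.1; 500 permutations and
#' 500 posterior-predictive replicates.
#'
#' @param ... named overrides of any field.
#' @return object of class \code{rtc_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    model = "ci",
    n_iter = 10000L,
    burn_in = 5000L,
    thin = 1L,
    seed = 1L,
    multicat_thresholds = c(-1.5, -0.5, 0.5, 1.5),
    multicat_baseline = NULL,       # NULL -> middle category
    focal_points = seq(-2, 2, by = 0.5),
    bandwidth_h = 1.1,
    n_permutations = 500L,
    n_ppc_replicates = 500L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$model <- match.arg(cfg$model, c("ci", "linear", "quadratic", "multicat"))
  cfg$n_iter <- as.integer(cfg$n_iter)
  cfg$burn_in <- as.integer(cfg$burn_in)
  cfg$thin <- as.integer(cfg$thin)
  if (cfg$n_iter < 1) stop("n_iter must be positive", call. = FALSE)
  if (cfg$burn_in < 0 || cfg$burn_in >= cfg$n_iter) {
    stop(sprintf("burn_in (%d) must be non-negative and < n_iter (%d)",
                 cfg$burn_in, cfg$n_iter), call. = FALSE)
  }
  if (cfg$thin < 1) stop("thin must be a positive integer", call. = FALSE)
  thr <- cfg$multicat_thresholds
  if (length(thr) < 1 || any(diff(thr) <= 0)) {
    stop("multicat_thresholds must be strictly ascending", call. = FALSE)
  }
  M <- length(thr) + 1L
  if (is.null(cfg$multicat_baseline)) cfg$multicat_baseline <- as.integer((M + 1L) %/% 2L)
  cfg$multicat_baseline <- as.integer(cfg$multicat_baseline)
  if (cfg$multicat_baseline < 1 || cfg$multicat_baseline > M) {
    stop("multicat_baseline out of range", call. = FALSE)
  }
  fp <- cfg$focal_points
  if (length(fp) < 2 || any(diff(fp) <= 0)) {
    stop("focal_points must be strictly ascending with at least 2 points", call. = FALSE)
  }
  if (cfg$bandwidth_h <= 0) stop("bandwidth_h must be positive", call. = FALSE)
  if (cfg$n_permutations < 1) stop("n_permutations must be positive", call. = FALSE)
  if (cfg$n_ppc_replicates < 1) stop("n_ppc_replicates must be positive", call. = FALSE)
  structure(cfg, class = "rtc_config")
}

#' Parse a run configuration from a JSON file
#'
#' Unspecified fields fall back to \code{\link{default_config}} defaults.
#' An empty document yields the full default configuration.
#'
#' @param path path to a JSON configuration file.
#' @return validated \code{rtc_config}.
#' @export
parse_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*(\\{|$)", txt)) {
    stop("configuration must be JSON (YAML is not supported in this build)",
         call. = FALSE)
  }
  vals <- if (grepl("\\{", txt)) jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  if (length(vals) == 0) vals <- list()
  do.call(default_config, vals)
}
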