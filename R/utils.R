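#' @importFrom stats rnorm rpois runif sd setNames aggregate
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head modifyList
NULL

# Deterministic child seed for a named stage / replicate. Keeps results
# reproducible from one user-facing seed while letting stages re-run
# independently. Always < 2^31.
child_seed <- function(seed, stage, index = 0L) {
  offsets <- c(
    images = 101L, qpcr = 211L, rppa = 307L, routes = 401L, mass = 503L,
    generic = 701L
  )
  off <- if (stage %in% names(offsets)) offsets[[stage]] else offsets[["generic"]]
  as.integer((as.numeric(seed) + 7919 * off + 104729 * index) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Write a data frame as tab-separated UTF-8 with a header row
#'
#' All tabular outputs of the pipeline go through this writer so that
#' repeated runs with the same seed are byte-identical.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) paste(signif(x, 8), collapse = ";"),
                        character(1))
    }
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 10)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table with a header row
#' @param path input path.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Path to a packaged fixture
#'
#' @param ... path components below `inst/extdata`.
#' @export
hq_fixture <- function(...) {
  p <- system.file("extdata", ..., package = "hippoquant")
  if (!nzchar(p)) stop("fixture not found: ", file.path(...), call. = FALSE)
  p
}

# Otsu threshold of a numeric vector (256-bin between-class variance
# maximiser). Used where the threshold must be computed on a masked subset,
# which EBImage::otsu (whole-image) cannot do.
otsu_vector <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= .Machine$double.eps) {
    stop("degenerate input: all values equal, Otsu threshold undefined",
         call. = FALSE)
  }
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w0c <- w0[-nbins]
  bc <- (mu_t * w0c - mu[-nbins])^2 / (w0c * (1 - w0c))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}
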