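#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join n row_number across all_of pull first last
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap list_rbind
#' @importFrom stats fft median sd approx rnorm runif setNames quantile
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# single place for stopping with a field name, used by config validators
abort_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "insolegait_config_error")
}

abort_data <- function(msg, class = "insolegait_data_error") {
  abort(msg, class = class)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == as.integer(x)

is_prop <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x <= 1

is_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0

# trapezoid integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# shoelace polygon area of the convex hull of a 2-D point set
convex_hull_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# rowwise max over a numeric matrix without apply() overhead
row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# centred moving average with edge replication (window must be odd)
moving_average <- function(x, window = 5L) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (half + 1):(half + length(x))]
}
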