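# small shared helpers

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit sub-seed derived from a master seed and a stage tag,
# so that each pipeline stage draws from its own reproducible stream
#' @noRd
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 2654435761 + h * 40503) %% 2147483647L)
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# odd kernel size in pixels for a physical kernel extent
#' @noRd
kernel_px <- function(size_um, pixel_pitch) {
  k <- round(size_um / pixel_pitch)
  k <- max(k, 3L)
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

#' @noRd
assert_matrix <- function(x, what = "map") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  invisible(x)
}

# stack a list of equally sized matrices into H x W x n
#' @noRd
stack_maps <- function(maps) {
  maps <- lapply(maps, map_values)
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("all maps must share the same dimensions", call. = FALSE)
  array(unlist(maps, use.names = FALSE), dim = c(d, length(maps)))
}

# accept a response_map or a bare matrix
#' @noRd
map_values <- function(x) {
  if (inherits(x, "response_map")) x$values else assert_matrix(x)
}

#' @noRd
map_pitch <- function(x, pixel_pitch = NULL) {
  if (!is.null(pixel_pitch)) return(pixel_pitch)
  if (inherits(x, "response_map") && !is.null(x$pixel_pitch)) return(x$pixel_pitch)
  stop("pixel_pitch is required (not carried by a bare matrix)", call. = FALSE)
}
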