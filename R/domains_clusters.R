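# Hue domains and hue clusters: turn significant regions into domains,
# assemble clusters from spatially overlapping domains, and compute the
# morphometrics (area, equivalent diameter, normalized area, completeness,
# peak arrangement).

#' Equivalent diameter of a region
#'
#' Diameter of the circle with the same area: `2 * sqrt(area / pi)`.
#'
#' @param area_um2 area(s) in square micrometers.
#' @return diameter(s) in micrometers.
#' @export
equivalent_diameter <- function(area_um2) {
  if (any(area_um2 < 0, na.rm = TRUE)) stop("area must be >= 0", call. = FALSE)
  2 * sqrt(area_um2 / pi)
}

#' Extract hue domains from significant region sets
#'
#' One hue domain per surviving significant region of the per-hue
#' (hue-vs-achromatic) statistical maps. Domains containing any
#' vessel-masked pixel are excluded. Areas are pixel counts times
#' `pixel_pitch^2`.
#'
#' @param regions_by_hue named list (names = hue angles) of `region_set`s
#'   from [cluster_extent_threshold()].
#' @param vessel optional [pixel_mask()]; domains intersecting its invalid
#'   pixels are dropped.
#' @param pixel_pitch micrometers per pixel.
#' @return list of class `hue_domain_set`: `domains` (data.frame with
#'   `domain_id`, `hue_deg`, `n_pixels`, `area_um2`, `equiv_diam_um`,
#'   `min_p`, `peak_row`, `peak_col`), `pixels` (list of pixel index
#'   vectors), `dim`, `pixel_pitch`.
#' @export
extract_domains <- function(regions_by_hue, vessel = NULL, pixel_pitch) {
  stopifnot(length(regions_by_hue) > 0)
  d <- dim(regions_by_hue[[1]]$labels)
  rows <- list(); pixels <- list(); id <- 0L
  for (h in names(regions_by_hue)) {
    rs <- regions_by_hue[[h]]
    if (!identical(dim(rs$labels), d))
      stop("region sets must share one grid", call. = FALSE)
    if (nrow(rs$table) == 0) next
    for (j in seq_len(nrow(rs$table))) {
      px <- which(rs$labels == rs$table$region_id[j])
      if (!is.null(vessel) && any(!vessel$valid[px])) next
      id <- id + 1L
      pixels[[id]] <- px
      rows[[id]] <- data.frame(
        domain_id = id, hue_deg = as.numeric(h),
        n_pixels = length(px),
        area_um2 = length(px) * pixel_pitch^2,
        equiv_diam_um = equivalent_diameter(length(px) * pixel_pitch^2),
        min_p = rs$table$min_p[j],
        peak_row = rs$table$peak_row[j], peak_col = rs$table$peak_col[j])
    }
  }
  domains <- if (id > 0) do.call(rbind, rows) else data.frame(
    domain_id = integer(0), hue_deg = numeric(0), n_pixels = integer(0),
    area_um2 = numeric(0), equiv_diam_um = numeric(0), min_p = numeric(0),
    peak_row = integer(0), peak_col = integer(0))
  structure(list(domains = domains, pixels = pixels, dim = d,
                 pixel_pitch = pixel_pitch),
            class = "hue_domain_set")
}

#' Assemble hue clusters from overlapping domains
#'
#' Builds the domain overlap graph (edge between two domains sharing at
#' least one pixel) and takes its connected components. Components covering
#' at least `min_hues` distinct hues are hue clusters; a cluster with all
#' `n_hues_total` hues is complete. Cluster area is the area of the union
#' footprint of its member domains. Components spanning more domains than
#' hues (merged clusters sharing domains) are not split; they are flagged
#' via `n_domains`.
#'
#' @param domain_set a `hue_domain_set` from [extract_domains()].
#' @param min_hues minimum number of distinct hues (default 4).
#' @param n_hues_total hues in the experiment (default 8).
#' @return list of class `hue_cluster_set`: `clusters` (data.frame with
#'   `cluster_id`, `n_domains`, `n_hues`, `complete`, `n_pixels`,
#'   `area_um2`), `membership` (data.frame `domain_id`, `cluster_id`;
#'   NA cluster for domains in sub-threshold components), `domain_set`.
#' @export
build_clusters <- function(domain_set, min_hues = 4, n_hues_total = 8) {
  dt <- domain_set$domains
  n <- nrow(dt)
  if (n == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(0), n_domains = integer(0),
                            n_hues = integer(0), complete = logical(0),
                            n_pixels = integer(0), area_um2 = numeric(0)),
      membership = data.frame(domain_id = integer(0), cluster_id = integer(0)),
      domain_set = domain_set), class = "hue_cluster_set"))
  }
  # overlap graph; order-invariant because components are relabeled by
  # smallest member domain id
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (length(intersect(domain_set$pixels[[i]], domain_set$pixels[[j]])))
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
  memb <- igraph::components(g)$membership
  comp_ids <- sort(unique(memb))
  # canonical order: by smallest domain_id in the component
  first_dom <- vapply(comp_ids, function(ci) min(dt$domain_id[memb == ci]),
                      numeric(1))
  comp_ids <- comp_ids[order(first_dom)]
  rows <- list(); membership <- data.frame(domain_id = dt$domain_id,
                                           cluster_id = NA_integer_)
  cid <- 0L
  for (ci in comp_ids) {
    sel <- memb == ci
    hues <- unique(dt$hue_deg[sel])
    if (length(hues) < min_hues) next
    cid <- cid + 1L
    membership$cluster_id[sel] <- cid
    upx <- unique(unlist(domain_set$pixels[which(sel)]))
    rows[[cid]] <- data.frame(
      cluster_id = cid, n_domains = sum(sel), n_hues = length(hues),
      complete = length(hues) == n_hues_total,
      n_pixels = length(upx),
      area_um2 = length(upx) * domain_set$pixel_pitch^2)
  }
  clusters <- if (cid > 0) do.call(rbind, rows) else data.frame(
    cluster_id = integer(0), n_domains = integer(0), n_hues = integer(0),
    complete = logical(0), n_pixels = integer(0), area_um2 = numeric(0))
  structure(list(clusters = clusters, membership = membership,
                 domain_set = domain_set),
            class = "hue_cluster_set")
}

#' Normalized domain area
#'
#' Area of each hue domain divided by the area of the hue cluster it belongs
#' to; in `(0, 1]`.
#'
#' @param cluster_set a `hue_cluster_set` from [build_clusters()].
#' @return data.frame with `domain_id`, `hue_deg`, `cluster_id`,
#'   `area_um2`, `cluster_area_um2`, `normalized_area` (NA for domains not
#'   in any cluster).
#' @export
normalized_domain_area <- function(cluster_set) {
  dt <- cluster_set$domain_set$domains
  m <- cluster_set$membership
  cl <- cluster_set$clusters
  out <- data.frame(domain_id = dt$domain_id, hue_deg = dt$hue_deg,
                    cluster_id = m$cluster_id, area_um2 = dt$area_um2)
  out$cluster_area_um2 <- cl$area_um2[match(out$cluster_id, cl$cluster_id)]
  out$normalized_area <- out$area_um2 / out$cluster_area_um2
  out
}

#' Completeness summary of hue clusters
#'
#' Counts complete vs incomplete clusters and the percentage incomplete
#' (reported to one decimal, as conventional).
#'
#' @param clusters a `hue_cluster_set`, or a data.frame with a logical
#'   `complete` column (optionally a grouping column named by `by`).
#' @param by optional name of a grouping column (e.g. cortical area).
#' @return data.frame with `n_total`, `n_complete`, `n_incomplete`,
#'   `pct_incomplete` (one group per row when `by` is given).
#' @export
completeness_summary <- function(clusters, by = NULL) {
  tab <- if (inherits(clusters, "hue_cluster_set")) clusters$clusters
         else clusters
  if (!"complete" %in% names(tab))
    stop("clusters must have a logical 'complete' column", call. = FALSE)
  one <- function(x) {
    n <- nrow(x); ni <- sum(!x$complete)
    data.frame(n_total = n, n_complete = n - ni, n_incomplete = ni,
               pct_incomplete = round(100 * ni / n, 1))
  }
  if (is.null(by)) return(one(tab))
  parts <- split(tab, tab[[by]])
  out <- do.call(rbind, lapply(parts, one))
  out <- cbind(setNames(data.frame(names(parts)), by), out)
  rownames(out) <- NULL
  out
}

#' Peak arrangement path of a hue cluster
#'
#' For each member domain of a cluster, takes its response peak point and
#' orders the peaks by hue angle, yielding the polyline that visualizes how
#' preference shifts across the cluster. When a hue has several member
#' domains the one with the smallest peak p is used.
#'
#' @param cluster_set a `hue_cluster_set`.
#' @param cluster_id which cluster.
#' @return data.frame (ordered by hue angle) with `hue_deg`, `domain_id`,
#'   `peak_row`, `peak_col`.
#' @export
arrangement_path <- function(cluster_set, cluster_id) {
  m <- cluster_set$membership
  dt <- cluster_set$domain_set$domains
  sel <- which(!is.na(m$cluster_id) & m$cluster_id == cluster_id)
  if (length(sel) == 0) stop("no such cluster: ", cluster_id, call. = FALSE)
  d <- dt[dt$domain_id %in% m$domain_id[sel], , drop = FALSE]
  # one peak per hue: smallest min_p wins
  d <- d[order(d$hue_deg, d$min_p), , drop = FALSE]
  d <- d[!duplicated(d$hue_deg), , drop = FALSE]
  data.frame(hue_deg = d$hue_deg, domain_id = d$domain_id,
             peak_row = d$peak_row, peak_col = d$peak_col)
}
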