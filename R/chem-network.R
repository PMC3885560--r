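#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits. Two empty fingerprints
#' are defined to have similarity 0 (with a warning): no shared chemistry is
#' claimable from no bits.
#'
#' @param a,b 0/1 vectors of equal length.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ", call. = FALSE)
  a <- as.logical(a)
  b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both fingerprints empty; similarity defined as 0")
    return(0)
  }
  sum(a & b) / uni
}

# all-pairs Tanimoto via bit counts: fast path used by build_network
tanimoto_matrix <- function(fps) {
  m <- as.matrix(fps)
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  sim
}

#' Build the OGTT-responsive chemical-similarity network
#'
#' One vertex per fingerprint, carrying its LV1 loading (`loading_lv1`),
#' the loading magnitude (`size`) and a direction attribute: `increase` for
#' loading > `eps`, `decrease` for loading < `-eps`, otherwise `unclear`
#' (also used when a loading is missing). An undirected edge joins every
#' pair with Tanimoto similarity strictly greater than `threshold` (a pair
#' at exactly the threshold gets no edge), weighted by the similarity.
#'
#' @param fps a [fingerprint_set()].
#' @param loadings named numeric vector of LV1 loadings (e.g. from
#'   [ogtt_time_model()]); ids without a loading become `unclear` vertices.
#' @param threshold edge threshold on Tanimoto similarity.
#' @param eps half-width of the "unclear" band around zero loading.
#' @return igraph graph; the connected-component summary is attached as
#'   attribute `"components"` (data.frame component, size).
#' @export
build_network <- function(fps, loadings = NULL, threshold = 0.7, eps = 0) {
  ids <- rownames(fps)
  if (length(ids) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "components") <- data.frame(component = integer(0),
                                        size = integer(0))
    return(g)
  }
  lv1 <- rep(NA_real_, length(ids))
  names(lv1) <- ids
  if (!is.null(loadings)) {
    common <- intersect(ids, names(loadings))
    lv1[common] <- loadings[common]
  }
  direction <- ifelse(is.na(lv1), "unclear",
                      ifelse(lv1 > eps, "increase",
                             ifelse(lv1 < -eps, "decrease", "unclear")))
  sim <- tanimoto_matrix(fps)
  pairs <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "loading_lv1", value = unname(lv1))
  g <- igraph::set_vertex_attr(g, "size", value = unname(abs(lv1)))
  g <- igraph::set_vertex_attr(g, "direction", value = unname(direction))
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, t(pairs))
    g <- igraph::set_edge_attr(g, "tanimoto",
                               value = sim[pairs])
  }
  comp <- igraph::components(g)
  attr(g, "components") <- data.frame(component = seq_len(comp$no),
                                      size = as.integer(comp$csize))
  g
}
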