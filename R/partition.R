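## Region partitioning of the structured surface.
##
## The 200 circumferential layers are grouped into 50 ordered regions:
## 12 in the ascending aorta / arch block (layers before the landmark) and
## 38 in the descending block (landmark layer through layer 200). Region 13
## always starts at the landmark layer. Block boundaries come from rounding
## equally spaced fractional boundaries, so region sizes within a block
## differ by at most one layer ("approximately equal-sized regions").

#' Partition structured-surface layers into 50 regions
#'
#' @param structured a `structured_surface`, or the number of layers.
#' @param landmark_layer layer index (1-based) where region 13 starts;
#'   defaults to the surface's landmark layer.
#' @param n_regions total number of regions.
#' @param n_ascending number of regions before the landmark.
#' @return object of class `region_partition`: data frame with columns
#'   `region`, `layer_start`, `layer_end`, `descending`.
#' @export
#' @examples
#' p <- partition_regions(200, landmark_layer = 49)
#' sum(p$descending)  # 38 descending regions
partition_regions <- function(structured, landmark_layer = NULL,
                              n_regions = 50L, n_ascending = 12L) {
  n_layers <- if (inherits(structured, "structured_surface")) {
    if (is.null(landmark_layer)) landmark_layer <- structured$landmark_layer
    structured$n_layers
  } else as.integer(structured)
  if (is.null(landmark_layer) || is.na(landmark_layer))
    stop("landmark_layer required")
  n_descending <- n_regions - n_ascending
  if (landmark_layer <= n_ascending)
    stop("landmark too close to the proximal end: cannot form ",
         n_ascending, " ascending regions")
  if (n_layers - landmark_layer + 1L < n_descending)
    stop("landmark too close to the distal end: cannot form ",
         n_descending, " descending regions")

  b_asc <- round(seq(1, landmark_layer, length.out = n_ascending + 1L))
  b_desc <- round(seq(landmark_layer, n_layers + 1L,
                      length.out = n_descending + 1L))
  if (any(diff(b_asc) < 1L) || any(diff(b_desc) < 1L))
    stop("degenerate partition: a region would be empty")
  starts <- c(b_asc[-(n_ascending + 1L)], b_desc[-(n_descending + 1L)])
  ends <- c(b_asc[-1L] - 1L, b_desc[-1L] - 1L)
  out <- data.frame(region = seq_len(n_regions),
                    layer_start = as.integer(starts),
                    layer_end = as.integer(ends),
                    descending = seq_len(n_regions) > n_ascending)
  class(out) <- c("region_partition", "data.frame")
  out
}

#' Layer indices of one region
#' @keywords internal
region_layers <- function(partition, region) {
  r <- partition[partition$region == region, ]
  seq(r$layer_start, r$layer_end)
}

#' Average a per-node field over the descending regions
#'
#' Arithmetic mean of the field over each descending region's nodes.
#' Non-finite node values (flagged invalid upstream) are excluded; a region
#' with no valid node yields `NA`.
#'
#' @param values matrix (n_layers x n_nodes) or vector of length
#'   n_layers*n_nodes (layer-major) of node values.
#' @param partition a `region_partition`.
#' @param n_nodes nodes per layer (needed when `values` is a vector).
#' @return named numeric vector, one mean per descending region.
#' @export
region_average <- function(values, partition, n_nodes = 50L) {
  if (is.null(dim(values))) {
    values <- matrix(values, ncol = n_nodes, byrow = FALSE)
  }
  desc <- partition[partition$descending, ]
  out <- vapply(seq_len(nrow(desc)), function(i) {
    v <- values[seq(desc$layer_start[i], desc$layer_end[i]), , drop = FALSE]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  names(out) <- desc$region
  out
}
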