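# Shared fixtures: all built in code at test time.

# angle between two vectors in degrees
vec_angle <- function(a, b) {
  acos(pmin(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# a horizontal 1-px line mask whose midline pixel count is exactly n
line_mask <- function(n, pad = 10) {
  m <- matrix(FALSE, 2 * pad, n + 2 * pad)
  m[pad, pad + seq_len(n)] <- TRUE
  m
}

# small reference phantom used across tests (fast to render/segment)
small_phantom <- function(seed = 1, ...) {
  render_he_phantom(skin_phantom_spec(seed = seed, ...))
}

# run segmentation + graph analysis on a phantom, returning the classified
# graph of the largest epidermal component plus the epidermis mask
analyze_phantom <- function(ph, min_path_px = 500) {
  em <- segment_epidermis(ph$image, color_filter_config("buttock"))
  tb <- boundary_index(ph$truth$tissue_mask, scope = "tissue")
  g <- analyze_component(em$labels == which.max(em$areas), tb,
                         min_path_px = min_path_px)
  list(graph = g, epidermis = em, tissue_boundary = tb)
}

# independent textbook Kruskal MST total weight (oracle for build_graph_and_mst)
kruskal_weight <- function(edges) {
  # edges: data.frame(a, b, w); returns total MST weight over all components
  parent <- seq_len(max(c(edges$a, edges$b)))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0
  for (i in order(edges$w)) {
    ra <- find(edges$a[i]); rb <- find(edges$b[i])
    if (ra != rb) { parent[ra] <- rb; total <- total + edges$w[i] }
  }
  total
}

# brute-force distribution summary (oracle for agg_stats): manual
# linear-interpolation percentiles on the sorted sample
brute_stats <- function(x) {
  x <- sort(x)
  n <- length(x)
  pct <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  c(mean = sum(x) / n,
    sd = sqrt(sum((x - sum(x) / n)^2) / (n - 1)),
    median = pct(0.5), iqr = pct(0.75) - pct(0.25),
    p5 = pct(0.05), p25 = pct(0.25), p75 = pct(0.75), p95 = pct(0.95),
    range = x[n] - x[1])
}

# random tree as node/branch tibbles (for longest-path oracle tests)
random_tree_graph <- function(n, seed) {
  withr::with_seed(seed, {
    parents <- vapply(2:n, function(v) sample(v - 1L, 1L), 1L)
    w <- sample(1:25, n - 1, replace = TRUE)
    nodes <- tibble::tibble(node_id = 1:n, kind = "junction",
                            centroid_r = 1, centroid_c = 1, n_pixels = 1L)
    branches <- tibble::tibble(branch_id = seq_len(n - 1), length = w,
                               node_a = pmin(2:n, parents),
                               node_b = pmax(2:n, parents))
    list(nodes = nodes, branches = branches)
  })
}

clip_unit <- function(x) pmin(pmax(x, 0), 1)
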