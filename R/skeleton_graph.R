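#' Skeletonize one epidermal component
#'
#' Morphological (Zhang-Suen) thinning to a 1-px-wide, 8-connected skeleton.
#' Deterministic: identical masks give identical skeletons.
#'
#' @param mask_component logical/0-1 matrix of one 8-connected component.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize_component <- function(mask_component) {
  m <- (mask_component > 0) * 1L
  .thin_zhang_suen(m) > 0
}

#' Detect junction/endpoint nodes and branches on a skeleton
#'
#' Neighbour counts are computed on skeleton pixels with the 3x3
#' 8-connectivity kernel (centre excluded): pixels with more than 2 skeleton
#' neighbours are junction pixels, pixels with exactly 1 are endpoints.
#' 8-adjacent clusters of junction pixels merge into a single junction node
#' whose centroid is the pixel mean (thinning commonly emits junction
#' clusters; merging prevents spurious zero-length branches); endpoint pixels
#' are one node each. Remaining
#' skeleton pixels are labelled into branches; only branches adjacent to
#' exactly two distinct nodes are retained.
#'
#' @param sk logical skeleton matrix.
#' @return list with `nodes` (tibble: node_id, kind, centroid_r, centroid_c,
#'   n_pixels), `branches` (tibble: branch_id, length, node_a, node_b),
#'   `node_map` and `branch_map` label matrices, and `branch_pixels` (list of
#'   coordinate matrices, indexed by branch_id).
#' @export
detect_nodes_and_branches <- function(sk) {
  nbr <- neighbor_sum8(sk * 1)
  junction <- sk & nbr > 2
  endpoint <- sk & nbr == 1
  jlab <- label_components(junction)
  # junction clusters merge into one node; endpoints stay one node per pixel
  elab <- matrix(0L, nrow(sk), ncol(sk))
  epx <- which(endpoint)
  elab[epx] <- seq_along(epx)
  nj <- max(jlab)
  node_map <- jlab
  node_map[elab > 0] <- elab[elab > 0] + nj
  n_nodes <- nj + max(elab)
  nodes <- if (n_nodes == 0L) {
    tibble::tibble(node_id = integer(), kind = character(),
                   centroid_r = numeric(), centroid_c = numeric(),
                   n_pixels = integer())
  } else {
    px <- which(node_map > 0, arr.ind = TRUE)
    id <- node_map[node_map > 0]
    tibble::tibble(
      node_id = sort(unique(id)),
      kind = ifelse(sort(unique(id)) <= nj, "junction", "endpoint"),
      centroid_r = as.numeric(tapply(px[, 1], id, mean)),
      centroid_c = as.numeric(tapply(px[, 2], id, mean)),
      n_pixels = as.integer(tapply(id, id, length))
    )
  }
  branch_mask <- sk & node_map == 0
  blab <- label_components(branch_mask)
  nb <- max(blab)
  branch_pixels <- vector("list", nb)
  keep <- logical(nb)
  node_a <- node_b <- integer(nb)
  len <- integer(nb)
  if (nb > 0L) {
    nr <- nrow(sk); nc <- ncol(sk)
    allpx <- which(blab > 0, arr.ind = TRUE)
    bid <- blab[blab > 0]
    for (b in seq_len(nb)) {
      bp <- allpx[bid == b, , drop = FALSE]
      branch_pixels[[b]] <- bp
      len[b] <- nrow(bp)
      adj <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- bp[, 1] + dr; cc <- bp[, 2] + dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        if (any(ok)) adj <- c(adj, node_map[cbind(rr[ok], cc[ok])])
      }
      adj <- sort(unique(adj[adj > 0]))
      if (length(adj) == 2L) {
        keep[b] <- TRUE
        node_a[b] <- adj[1]; node_b[b] <- adj[2]
      }
    }
  }
  branches <- tibble::tibble(
    branch_id = seq_len(nb), length = len,
    node_a = node_a, node_b = node_b
  )[keep, ]
  list(nodes = nodes, branches = branches, node_map = node_map,
       branch_map = blab, branch_pixels = branch_pixels)
}

#' Build the weighted epidermis graph and its minimum spanning tree
#'
#' Nodes become vertices and branches become edges weighted by branch length
#' (pixel count). Parallel edges collapse to the lighter one (ties by lower
#' branch id); the MST is computed per connected component. Ties among equal
#' MST weights are broken deterministically by `(weight, branch_id)` via an
#' infinitesimal id-ordered perturbation.
#'
#' @param nodes,branches as returned by [detect_nodes_and_branches()] (the
#'   full list can also be passed as `nodes` with `branches` missing).
#' @return `epidermis_graph`: list with `nodes`, `branches`, `graph` (igraph),
#'   `mst` (igraph) plus the skeleton maps when available.
#' @export
build_graph_and_mst <- function(nodes, branches = NULL) {
  maps <- NULL
  if (is.list(nodes) && !is.data.frame(nodes) && is.null(branches)) {
    maps <- nodes
    branches <- nodes$branches
    nodes <- nodes$nodes
  }
  stopifnot(nrow(nodes) >= 1L)
  br <- dplyr::arrange(branches, .data$length, .data$branch_id)
  key <- paste(pmin(br$node_a, br$node_b), pmax(br$node_a, br$node_b))
  br <- br[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(br$node_a), to = as.character(br$node_b),
               weight = br$length, branch_id = br$branch_id),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id))
  )
  w <- igraph::E(g)$weight + rank(igraph::E(g)$branch_id) * 1e-7
  mst <- igraph::mst(g, weights = w)
  structure(list(nodes = nodes, branches = br, graph = g, mst = mst,
                 maps = maps),
            class = "epidermis_graph")
}

#' @export
print.epidermis_graph <- function(x, ...) {
  cat("<epidermis_graph> ", nrow(x$nodes), " nodes, ", nrow(x$branches),
      " branches", sep = "")
  if (!is.null(x$midline)) {
    cat("; midline ", x$midline$length_px, " px, ",
        sum(x$ridges$valid %||% logical(0)), " valid ridge(s)",
        if (isTRUE(x$accepted)) "" else " [REJECTED]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# farthest vertex from src on a weighted tree; ties -> lowest vertex name
farthest_vertex <- function(tree, src, within = igraph::V(tree)) {
  d <- igraph::distances(tree, v = src, to = within,
                         weights = igraph::E(tree)$weight)[1, ]
  d[!is.finite(d)] <- -Inf
  ids <- as.integer(names(d))
  best <- which(d == max(d))
  best <- best[order(ids[best])][1]
  list(vertex = names(d)[best], dist = max(d))
}

#' Longest (diameter) path of the epidermis graph
#'
#' Two-pass sweep on the MST: from the lowest-id vertex, find the farthest
#' vertex by summed edge weights, then the farthest vertex from that; the
#' connecting path is the tree diameter. Computed per connected component; the
#' global maximum is returned. Ties are broken by lowest vertex id.
#'
#' @param g an [build_graph_and_mst()] result.
#' @return list with `vertices` (ordered ids), `edge_branch_ids`, `weight`.
#' @export
longest_path <- function(g) {
  stopifnot(inherits(g, "epidermis_graph"))
  mst <- g$mst
  comp <- igraph::components(mst)
  best <- list(vertices = character(0), edge_branch_ids = integer(0),
               weight = 0)
  for (ci in seq_len(comp$no)) {
    vs <- igraph::V(mst)[comp$membership == ci]
    if (length(vs) == 1L) {
      cand <- list(vertices = names(vs), edge_branch_ids = integer(0),
                   weight = 0)
    } else {
      ids <- as.integer(names(vs))
      src <- names(vs)[which.min(ids)]
      a <- farthest_vertex(mst, src, vs)
      b <- farthest_vertex(mst, a$vertex, vs)
      sp <- igraph::shortest_paths(mst, from = a$vertex, to = b$vertex,
                                   weights = igraph::E(mst)$weight,
                                   output = "both")
      cand <- list(vertices = names(sp$vpath[[1]]),
                   edge_branch_ids = igraph::edge_attr(mst, "branch_id",
                                                       sp$epath[[1]]),
                   weight = b$dist)
    }
    take <- cand$weight > best$weight ||
      (cand$weight == best$weight && length(best$vertices) == 0L)
    if (take) best <- cand
  }
  best
}

#' Boundary index for nearest-boundary distance queries
#'
#' Boundary pixels are mask pixels 8-adjacent to background of the scope mask
#' (tissue or epidermal component); a precomputed exact Euclidean distance
#' map answers nearest-boundary queries in O(1).
#'
#' @param mask logical scope mask.
#' @param scope `"tissue"` or `"epidermis"` (provenance only).
#' @return `boundary_index` with `boundary` (coordinate matrix), `distmap`,
#'   `scope`.
#' @export
boundary_index <- function(mask, scope = c("tissue", "epidermis")) {
  scope <- match.arg(scope)
  b <- mask_boundary(mask)
  structure(list(boundary = which(b, arr.ind = TRUE),
                 distmap = dist_to_set(b), scope = scope),
            class = "boundary_index")
}

#' Nearest-boundary distance at (possibly fractional) pixel coordinates
#' @param bi a [boundary_index()].
#' @param r,c row/column coordinates (vectors allowed).
#' @return numeric distances (px), discretized to the pixel grid.
#' @export
boundary_distance <- function(bi, r, c) {
  rr <- pmin(pmax(round(r), 1), nrow(bi$distmap))
  cc <- pmin(pmax(round(c), 1), ncol(bi$distmap))
  bi$distmap[cbind(rr, cc)]
}

#' Classify midline vs rete-ridge edges and validate ridges
#'
#' Marks the longest-path edges as the epidermal midline; every other MST edge
#' is a provisional rete ridge. Components whose midline is shorter than
#' `min_path_px` midline pixels are rejected outright (no features emitted).
#' Each provisional ridge is validated directionally: with `d_tip` the
#' nearest-boundary distance of the tip and `d_base` that of its base
#' (junction), the ridge is valid iff `d_tip >= d_base` -- a tip strictly
#' closer to the (outer) boundary marks a spur pointing at the surface, not a
#' dermis-pointing rete ridge.
#'
#' @param g an `epidermis_graph` (after [build_graph_and_mst()]).
#' @param tissue_boundary a [boundary_index()] (tissue scope by default; an
#'   epidermal-boundary index may be supplied instead).
#' @param min_path_px rejection threshold on the midline pixel count,
#'   default 500.
#' @return the graph with `midline`, `ridges` (tibble: branch_id, base/tip
#'   nodes and centroids, d_base, d_tip, valid, reason) and `accepted` filled.
#' @export
classify_and_validate <- function(g, tissue_boundary, min_path_px = 500) {
  stopifnot(inherits(g, "epidermis_graph"),
            inherits(tissue_boundary, "boundary_index"))
  lp <- longest_path(g)
  midline_px <- midline_pixels(g, lp)
  g$midline <- list(vertices = lp$vertices,
                    edge_branch_ids = lp$edge_branch_ids,
                    weight = lp$weight,
                    pixels = midline_px,
                    length_px = nrow(midline_px))
  g$accepted <- nrow(midline_px) >= min_path_px
  g$min_path_px <- min_path_px
  mst_bids <- igraph::E(g$mst)$branch_id
  ridge_bids <- setdiff(mst_bids, lp$edge_branch_ids)
  if (!g$accepted || length(ridge_bids) == 0L) {
    g$ridges <- empty_ridge_tbl()
    return(g)
  }
  mid_set <- lp$vertices
  dist_to_mid <- rep(Inf, igraph::vcount(g$mst))
  names(dist_to_mid) <- igraph::V(g$mst)$name
  if (length(mid_set) > 0) {
    dm <- igraph::distances(g$mst, v = mid_set,
                            weights = igraph::E(g$mst)$weight)
    dist_to_mid[colnames(dm)] <- apply(dm, 2L, min)
  }
  rows <- lapply(ridge_bids, function(bid) {
    e <- igraph::E(g$mst)[igraph::E(g$mst)$branch_id == bid]
    ends <- igraph::ends(g$mst, e)[1, ]
    on_mid <- ends %in% mid_set
    base <- if (sum(on_mid) == 1L) ends[on_mid] else {
      ends[order(dist_to_mid[ends], as.integer(ends))][1]
    }
    tip <- setdiff(ends, base)[1]
    nb <- g$nodes[g$nodes$node_id == as.integer(base), ]
    nt <- g$nodes[g$nodes$node_id == as.integer(tip), ]
    d_base <- boundary_distance(tissue_boundary, nb$centroid_r, nb$centroid_c)
    d_tip <- boundary_distance(tissue_boundary, nt$centroid_r, nt$centroid_c)
    # a rete ridge terminates at a skeleton endpoint; junction-tipped edges
    # are internal connectors within a chain, not ridges of their own
    if (nt$kind != "endpoint") {
      valid <- FALSE; reason <- "internal_connector"
    } else if (d_tip >= d_base) {
      valid <- TRUE; reason <- "valid"
    } else {
      valid <- FALSE; reason <- "tip_closer_to_boundary"
    }
    tibble::tibble(
      branch_id = bid, length = e$weight,
      base_node = as.integer(base), tip_node = as.integer(tip),
      base_r = nb$centroid_r, base_c = nb$centroid_c,
      tip_r = nt$centroid_r, tip_c = nt$centroid_c,
      d_base = d_base, d_tip = d_tip, valid = valid,
      reason = reason
    )
  })
  g$ridges <- dplyr::bind_rows(rows)
  g
}

empty_ridge_tbl <- function() {
  tibble::tibble(branch_id = integer(), length = numeric(),
                 base_node = integer(), tip_node = integer(),
                 base_r = numeric(), base_c = numeric(),
                 tip_r = numeric(), tip_c = numeric(),
                 d_base = numeric(), d_tip = numeric(),
                 valid = logical(), reason = character())
}

# All skeleton pixels on the midline: branch pixels of midline edges plus
# member pixels of midline vertices.
midline_pixels <- function(g, lp) {
  px <- matrix(numeric(0), 0, 2)
  if (!is.null(g$maps)) {
    bp <- g$maps$branch_pixels[lp$edge_branch_ids]
    if (length(bp)) px <- do.call(rbind, bp)
    if (length(lp$vertices)) {
      nm <- g$maps$node_map
      sel <- nm
      sel[] <- nm %in% as.integer(lp$vertices)
      px <- rbind(px, which(sel > 0, arr.ind = TRUE))
    }
  }
  colnames(px) <- c("row", "col")
  px
}

#' Full skeleton-graph analysis of one epidermal component
#'
#' Chains [skeletonize_component()], [detect_nodes_and_branches()],
#' [build_graph_and_mst()] and [classify_and_validate()].
#'
#' @param component_mask logical mask of one epidermal component.
#' @param boundary a [boundary_index()] used for ridge validation (typically
#'   the whole-slice tissue boundary, making the rule a directional filter
#'   that keeps dermis-pointing branches; an epidermal-scope index may be
#'   passed instead).
#' @param min_path_px midline rejection threshold, default 500.
#' @return a classified `epidermis_graph` (with `skeleton` attached), or
#'   `NULL` for an empty mask.
#' @export
analyze_component <- function(component_mask, boundary, min_path_px = 500) {
  if (!any(component_mask)) return(NULL)
  sk <- skeletonize_component(component_mask)
  nb <- detect_nodes_and_branches(sk)
  if (nrow(nb$nodes) == 0L) {
    # degenerate skeleton (e.g. a small loop): no endpoints/junctions
    g <- structure(list(nodes = nb$nodes, branches = nb$branches,
                        maps = nb, accepted = FALSE,
                        midline = list(pixels = matrix(numeric(0), 0, 2),
                                       length_px = 0L),
                        ridges = empty_ridge_tbl()),
                   class = "epidermis_graph")
    g$skeleton <- sk
    return(g)
  }
  g <- build_graph_and_mst(nb)
  g <- classify_and_validate(g, boundary, min_path_px = min_path_px)
  g$skeleton <- sk
  g$component_mask <- component_mask
  g
}
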