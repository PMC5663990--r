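#' Centerline graphs
#'
#' A vessel centerline is represented as a tree of branches: polylines in
#' world coordinates (mm) meeting at bifurcation nodes, rooted at the vessel
#' inlet. `centerline_graph()` is the low-level constructor used both by the
#' phantom generator (ground-truth trees) and by [build_centerline_graph()]
#' (trees recovered from a skeletonized vessel mask).
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (mm) and `kind`
#'   (`"root"`, `"bifurcation"` or `"endpoint"`).
#' @param branches list of branches; each a list with `id` (integer), `from`
#'   and `to` (node ids, oriented away from the root), `points` (n x 3
#'   matrix, mm, ordered from `from` to `to`), `parent` (branch id or `NA`
#'   for generation-1 branches) and `generation` (1 = branches incident to
#'   the root).
#' @param root id of the root node.
#' @return object of class `centerline_graph`.
#' @export
centerline_graph <- function(nodes, branches, root) {
  stopifnot(is.data.frame(nodes), is.list(branches))
  ids <- vapply(branches, function(b) b$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate branch ids", call. = FALSE)
  structure(list(nodes = nodes, branches = branches, root = root),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  gen <- branch_generations(x)
  cat(sprintf("<centerline_graph> %d branches, %d nodes, depth %d, root node %d\n",
              length(x$branches), nrow(x$nodes),
              if (length(gen)) max(gen) else 0L, x$root))
  invisible(x)
}

branch_ids <- function(graph) vapply(graph$branches, function(b) b$id, integer(1))

#' Generation number of every branch (1 = incident to the root)
#' @param graph a [centerline_graph()].
#' @return named integer vector, branch id -> generation.
#' @export
branch_generations <- function(graph) {
  setNames(vapply(graph$branches, function(b) as.integer(b$generation), integer(1)),
           branch_ids(graph))
}

branch_parents <- function(graph) {
  setNames(vapply(graph$branches, function(b) as.integer(b$parent), integer(1)),
           branch_ids(graph))
}

#' Total polyline length of every branch, in mm
#' @param graph a [centerline_graph()].
#' @export
branch_lengths <- function(graph) {
  setNames(vapply(graph$branches, function(b) {
    p <- b$points
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1)), branch_ids(graph))
}

# insert points so that consecutive vertices are at most step_mm apart
densify_polyline <- function(points, step_mm) {
  if (nrow(points) < 2) return(points)
  out <- list(points[1, , drop = FALSE])
  for (i in 2:nrow(points)) {
    a <- points[i - 1, ]; b <- points[i, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step_mm))
    t <- seq_len(nseg) / nseg
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

# all branch polylines densified to <= step_mm vertex spacing, ordered by
# ascending branch id (the order the nearest-point tie-break relies on);
# returns list(points = n x 3 matrix, branch = integer vector)
graph_points <- function(graph, step_mm = 1) {
  ord <- order(branch_ids(graph))
  pts <- list(); ids <- list()
  for (k in seq_along(ord)) {
    b <- graph$branches[[ord[k]]]
    p <- densify_polyline(b$points, step_mm)
    pts[[k]] <- p
    ids[[k]] <- rep(b$id, nrow(p))
  }
  list(points = do.call(rbind, pts), branch = unlist(ids))
}

#' Build a centerline graph from a skeleton voxel set
#'
#' Classifies skeleton voxels by their number of 26-neighbors (1 =
#' endpoint, >= 3 = ramification), merges touching ramification voxels into
#' single bifurcation nodes, and traces maximal junction-free voxel chains
#' into branch polylines (voxel centers, mm). Cycles left by thinning
#' artifacts are broken by dropping the shortest cycle edge (maximum
#' spanning tree on branch length), with a warning. The tree is then rooted
#' and every branch oriented away from the root, with generation numbers
#' (1 = branches incident to the root).
#'
#' @param skeleton binary [as_volume()] of single-voxel-wide centerlines.
#' @param spacing_mm voxel spacing (defaults to the volume's).
#' @param root_hint optional length-3 position in mm; the node nearest to it
#'   becomes the root. Defaults to the endpoint node with the lowest id.
#' @param prune_mm terminal branches shorter than this are removed (thinning
#'   spurs at junctions and tube walls); pass-through nodes left behind are
#'   merged. Default two voxel diagonals; 0 disables pruning.
#' @return a [centerline_graph()].
#' @export
build_centerline_graph <- function(skeleton, spacing_mm = NULL, root_hint = NULL,
                                   prune_mm = NULL) {
  spacing <- spacing_or(skeleton, spacing_mm)
  sk <- which(as.logical(vol_data(skeleton)))
  if (length(sk) == 0) stop("empty centerline", call. = FALSE)
  d <- dim(skeleton)
  arr_idx <- arrayInd(sk, d)
  nvox <- length(sk)

  # 26-neighbor lists as indices into 1..nvox
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  lut <- integer(prod(d)); lut[sk] <- seq_len(nvox)
  nbrs <- vector("list", nvox)
  for (r in seq_len(nrow(off))) {
    sh <- sweep(arr_idx, 2, off[r, ], "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    lin <- rep(0L, nvox)
    lin[ok] <- lut[(sh[ok, 3] - 1L) * d[1] * d[2] + (sh[ok, 2] - 1L) * d[1] + sh[ok, 1]]
    hit <- which(lin > 0L)
    for (i in hit) nbrs[[i]] <- c(nbrs[[i]], lin[i])
  }
  deg <- lengths(nbrs)

  # node voxels: endpoints, isolated voxels and ramifications
  is_nodevox <- deg != 2L
  node_of <- integer(nvox) # voxel -> node id
  nn <- 0L
  # merge touching ramification voxels into one node (26-connected clusters)
  junc <- which(deg >= 3L)
  seen <- logical(nvox)
  for (v in junc) {
    if (seen[v]) next
    nn <- nn + 1L
    stack <- v; seen[v] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      node_of[cur] <- nn
      nxt <- nbrs[[cur]]
      nxt <- nxt[deg[nxt] >= 3L & !seen[nxt]]
      if (length(nxt)) { seen[nxt] <- TRUE; stack <- c(stack, nxt) }
    }
  }
  for (v in which(deg <= 1L)) { nn <- nn + 1L; node_of[v] <- nn }

  coords_mm <- sweep(arr_idx - 0.5, 2, spacing, "*")
  trace_edges <- function() {
    edges <- list()
    chain_used <- logical(nvox)
    pair_seen <- new.env(hash = TRUE)
    for (v in which(is_nodevox & node_of > 0L)) {
      for (w in nbrs[[v]]) {
        if (is_nodevox[w]) {
          if (node_of[w] == node_of[v]) next # internal cluster edge
          key <- paste(sort(c(v, w)), collapse = "-")
          if (!is.null(pair_seen[[key]])) next
          pair_seen[[key]] <- TRUE
          edges[[length(edges) + 1L]] <- list(path = c(v, w))
        } else {
          if (chain_used[w]) next
          path <- c(v, w); chain_used[w] <- TRUE
          prev <- v; cur <- w
          repeat {
            nxt <- setdiff(nbrs[[cur]], prev)
            if (length(nxt) == 0L) break
            nxt <- nxt[1L]
            path <- c(path, nxt)
            if (is_nodevox[nxt]) break
            chain_used[nxt] <- TRUE
            prev <- cur; cur <- nxt
          }
          edges[[length(edges) + 1L]] <- list(path = path)
        }
      }
    }
    # pure degree-2 cycles with no node voxel: promote a voxel to a node
    leftover <- which(deg == 2L & !chain_used & node_of == 0L)
    # exclude voxels already part of traced paths between nodes
    if (length(leftover)) {
      for (v in leftover) {
        if (chain_used[v] || node_of[v] > 0L) next
        nn <<- nn + 1L; node_of[v] <<- nn; is_nodevox[v] <<- TRUE
        # trace the loop from v
        w <- nbrs[[v]][1L]
        path <- c(v, w); chain_used[w] <- TRUE
        prev <- v; cur <- w
        repeat {
          nxt <- setdiff(nbrs[[cur]], prev)
          if (length(nxt) == 0L) break
          nxt <- nxt[1L]
          path <- c(path, nxt)
          if (is_nodevox[nxt]) break
          chain_used[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        edges[[length(edges) + 1L]] <- list(path = path)
      }
    }
    edges
  }
  edges <- trace_edges()

  # node table: junction clusters at their centroid, others at the voxel
  node_pos <- matrix(0, nn, 3)
  for (k in seq_len(nn)) {
    mem <- which(node_of == k)
    node_pos[k, ] <- colMeans(coords_mm[mem, , drop = FALSE])
  }
  node_kind <- rep("endpoint", nn)
  for (k in seq_len(nn)) {
    mem <- which(node_of == k)
    if (any(deg[mem] >= 3L)) node_kind[k] <- "bifurcation"
  }

  branches <- lapply(seq_along(edges), function(i) {
    path <- edges[[i]]$path
    list(id = i,
         from = node_of[path[1L]],
         to = node_of[path[length(path)]],
         points = coords_mm[path, , drop = FALSE],
         parent = NA_integer_, generation = NA_integer_)
  })

  # break cycles: keep the maximum-length spanning tree
  elen <- vapply(branches, function(b) {
    p <- b$points
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1))
  g <- igraph::graph_from_edgelist(
    cbind(vapply(branches, `[[`, 0L, "from"), vapply(branches, `[[`, 0L, "to")),
    directed = FALSE)
  if (igraph::vcount(g) < nn) g <- igraph::add_vertices(g, nn - igraph::vcount(g))
  keep <- seq_along(branches)
  if (length(branches) >= igraph::vcount(g)) {
    tr <- igraph::mst(g, weights = max(elen) + 1 - elen)
    # identify kept branches by matching endpoint pairs greedily
    used <- logical(length(branches))
    tre <- igraph::as_edgelist(tr)
    keep <- integer(0)
    for (r in seq_len(nrow(tre))) {
      cand <- which(!used &
        ((vapply(branches, `[[`, 0L, "from") == tre[r, 1] &
          vapply(branches, `[[`, 0L, "to") == tre[r, 2]) |
         (vapply(branches, `[[`, 0L, "from") == tre[r, 2] &
          vapply(branches, `[[`, 0L, "to") == tre[r, 1])))
      if (length(cand)) {
        pick <- cand[which.max(elen[cand])]
        used[pick] <- TRUE
        keep <- c(keep, pick)
      }
    }
    keep <- sort(keep)
    if (length(keep) < length(branches))
      warning(sprintf("centerline contained %d cycle edge(s); shortest removed",
                      length(branches) - length(keep)), call. = FALSE)
  }
  branches <- branches[keep]

  if (is.null(prune_mm)) prune_mm <- 2 * sqrt(sum(spacing^2))
  branches <- prune_spurs(branches, prune_mm)

  # rebuild the node set from the surviving branches
  used <- sort(unique(c(vapply(branches, `[[`, 0L, "from"),
                        vapply(branches, `[[`, 0L, "to"))))
  remap <- setNames(seq_along(used), used)
  degree <- table(factor(c(vapply(branches, `[[`, 0L, "from"),
                           vapply(branches, `[[`, 0L, "to")), levels = used))
  new_pos <- node_pos[used, , drop = FALSE]
  nodes <- data.frame(id = seq_along(used),
                      x = new_pos[, 1], y = new_pos[, 2], z = new_pos[, 3],
                      kind = ifelse(as.integer(degree) >= 3, "bifurcation", "endpoint"))
  branches <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    b$id <- i
    b$from <- unname(remap[as.character(b$from)])
    b$to <- unname(remap[as.character(b$to)])
    b
  })

  # choose root
  if (!is.null(root_hint)) {
    dists <- sqrt(rowSums(sweep(new_pos, 2, root_hint, "-")^2))
    root <- which.min(dists)
  } else {
    ep <- which(nodes$kind == "endpoint")
    root <- if (length(ep)) ep[1L] else 1L
  }
  nodes$kind[root] <- "root"

  g <- centerline_graph(nodes, branches, root)
  orient_graph(g)
}

# iteratively drop terminal branches shorter than prune_mm (never the last
# branch) and fuse the two branches around any degree-2 node into one
prune_spurs <- function(branches, prune_mm) {
  plen <- function(b) {
    p <- b$points
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }
  repeat {
    if (length(branches) <= 1L) break
    ends <- c(vapply(branches, `[[`, 0L, "from"), vapply(branches, `[[`, 0L, "to"))
    degree <- table(ends)
    deg_of <- function(n) as.integer(degree[as.character(n)])
    changed <- FALSE

    if (prune_mm > 0) {
      is_spur <- vapply(branches, function(b) {
        (deg_of(b$from) == 1L || deg_of(b$to) == 1L) && plen(b) < prune_mm
      }, logical(1))
      # keep at least one branch, and only prune spurs hanging off junctions
      at_junction <- vapply(branches, function(b) {
        deg_of(b$from) >= 3L || deg_of(b$to) >= 3L
      }, logical(1))
      drop <- is_spur & at_junction
      if (any(drop) && sum(!drop) >= 1L) {
        branches <- branches[!drop]
        changed <- TRUE
      }
    }

    # merge around pass-through nodes
    ends <- c(vapply(branches, `[[`, 0L, "from"), vapply(branches, `[[`, 0L, "to"))
    degree <- table(ends)
    pass <- as.integer(names(degree)[degree == 2L])
    for (nd in pass) {
      inc <- which(vapply(branches, function(b) b$from == nd || b$to == nd, logical(1)))
      if (length(inc) != 2L) next # self-loop or stale
      b1 <- branches[[inc[1]]]; b2 <- branches[[inc[2]]]
      # orient b1 to end at nd, b2 to start at nd
      if (b1$from == nd) {
        b1$points <- b1$points[rev(seq_len(nrow(b1$points))), , drop = FALSE]
        b1$from <- b1$to; b1$to <- nd
      }
      if (b2$to == nd) {
        b2$points <- b2$points[rev(seq_len(nrow(b2$points))), , drop = FALSE]
        b2$to <- b2$from; b2$from <- nd
      }
      if (b1$from == b1$to || b2$from == b2$to) next
      fused <- b1
      fused$to <- b2$to
      fused$points <- rbind(b1$points, b2$points[-1, , drop = FALSE])
      branches[[inc[1]]] <- fused
      branches <- branches[-inc[2]]
      changed <- TRUE
      break # degrees are stale; restart the scan
    }
    if (!changed) break
  }
  branches
}

# orient branches away from the root; assign parent branch and generation
orient_graph <- function(graph) {
  n_nodes <- nrow(graph$nodes)
  inc <- vector("list", n_nodes)
  for (i in seq_along(graph$branches)) {
    b <- graph$branches[[i]]
    inc[[b$from]] <- c(inc[[b$from]], i)
    inc[[b$to]] <- c(inc[[b$to]], i)
  }
  visited_nodes <- logical(n_nodes)
  visited_nodes[graph$root] <- TRUE
  queue <- list(list(node = graph$root, parent_branch = NA_integer_, gen = 0L))
  branches <- graph$branches
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (i in inc[[cur$node]]) {
      b <- branches[[i]]
      if (!is.na(b$generation)) next
      other <- if (b$from == cur$node) b$to else b$from
      if (b$to == cur$node) { # flip orientation
        b$to <- b$from; b$from <- cur$node
        b$points <- b$points[rev(seq_len(nrow(b$points))), , drop = FALSE]
      }
      b$parent <- cur$parent_branch
      b$generation <- cur$gen + 1L
      branches[[i]] <- b
      if (!visited_nodes[other]) {
        visited_nodes[other] <- TRUE
        queue[[length(queue) + 1L]] <-
          list(node = other, parent_branch = b$id, gen = b$generation)
      }
    }
  }
  if (any(is.na(vapply(branches, function(b) as.integer(b$generation), integer(1)))))
    warning("centerline graph is not connected; unreachable branches kept at generation NA",
            call. = FALSE)
  centerline_graph(graph$nodes, branches, graph$root)
}

#' Group branches into territories
#'
#' Either an explicit `map` (named vector, names = branch ids, values =
#' territory labels) or grouping by subtree: every branch is assigned to the
#' subtree rooted at its generation-`generation` ancestor. Branches closer
#' to the root than `generation` (shared trunk) join the lowest-id territory
#' root among their descendants; leaves shallower than `generation` form
#' their own territory. If `generation` exceeds the tree depth, every leaf
#' branch becomes its own territory, with a warning.
#'
#' @param graph a [centerline_graph()].
#' @param generation subtree generation (>= 1) at which territories start.
#' @param map explicit branch-to-territory assignment; overrides `generation`.
#' @return named integer vector: branch id -> territory id (1..k).
#' @export
group_branches <- function(graph, generation = 2L, map = NULL) {
  ids <- sort(branch_ids(graph))
  if (!is.null(map)) {
    if (!all(as.character(ids) %in% names(map)))
      stop("explicit map must cover every branch id", call. = FALSE)
    terr <- map[as.character(ids)]
    lev <- unique(terr)
    return(setNames(as.integer(factor(terr, levels = lev)), ids))
  }
  g <- as.integer(generation)
  if (is.na(g) || g < 1L) stop("generation must be >= 1", call. = FALSE)
  gen <- branch_generations(graph)[as.character(ids)]
  par <- branch_parents(graph)[as.character(ids)]
  depth <- max(gen, na.rm = TRUE)
  if (g > depth)
    warning(sprintf("generation %d exceeds tree depth %d; one territory per leaf branch",
                    g, depth), call. = FALSE)
  children <- split(ids, factor(par[as.character(ids)], levels = ids))
  is_leaf <- lengths(children)[as.character(ids)] == 0L

  # territory roots: branches at generation g, plus leaves shallower than g
  roots <- ids[(gen == g) | (is_leaf & gen < g)]
  root_of <- setNames(rep(NA_integer_, length(ids)), ids)
  ancestor_at <- function(b, target_gen) {
    while (gen[as.character(b)] > target_gen) b <- par[as.character(b)]
    b
  }
  # descend: trunk branches join the dominant (largest total centerline
  # length) descendant subtree -- a geometric criterion, stable under
  # branch relabeling; exact ties fall back to the lowest branch id
  blen <- branch_lengths(graph)[as.character(ids)]
  subtree_len <- function(b) {
    blen[as.character(b)] + sum(vapply(children[[as.character(b)]],
                                       subtree_len, numeric(1)))
  }
  subtree_root <- function(b) {
    if (b %in% roots) return(b)
    kids <- children[[as.character(b)]]
    if (!length(kids)) return(NA_integer_)
    lens <- vapply(kids, subtree_len, numeric(1))
    for (k in kids[order(-lens, kids)]) {
      r <- subtree_root(k)
      if (!is.na(r)) return(r)
    }
    NA_integer_
  }
  for (b in ids) {
    root_of[as.character(b)] <-
      if (gen[as.character(b)] >= g) ancestor_at(b, g) else subtree_root(b)
  }
  lev <- sort(unique(root_of))
  setNames(as.integer(factor(root_of, levels = lev)), ids)
}
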