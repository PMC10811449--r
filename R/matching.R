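# Bipartite one-to-one matching used by the linkage resolver.
#
# Objective: maximum cardinality first, then maximum total edge weight among
# maximum-cardinality matchings. Edges are processed in canonical
# (left, right) order, so the result is a pure function of the edge *set* —
# permuting the input changes nothing.
#
# Strategy: split the graph into connected components (union-find) and run
# successive-shortest-path min-cost augmentation per component with integer
# costs (cost = -weight). Each augmentation raises cardinality by one at
# minimum cost, which yields the lexicographic (cardinality, weight)
# optimum exactly.

.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# edges: data.frame with columns li, ri (1-based left/right indices), w
# n_left, n_right: node counts. Returns integer vector match_l (0 = unmatched)
.match_component <- function(li, ri, w, lefts, rights) {
  nl <- length(lefts); nr <- length(rights)
  # adjacency: for each left node, its incident edge indices (canonical order)
  adj <- vector("list", nl)
  for (k in seq_along(li)) adj[[li[k]]] <- c(adj[[li[k]]], k)
  match_l <- integer(nl)   # right index matched to left, 0 = free
  match_r <- integer(nr)
  edge_of_l <- integer(nl) # edge used by current match of left node

  repeat {
    # Bellman-Ford from all free left nodes over the residual graph
    INF <- .Machine$double.xmax
    dist_l <- rep(INF, nl); dist_r <- rep(INF, nr)
    pred_r <- integer(nr)   # edge index used to reach right node
    dist_l[match_l == 0L] <- 0
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (k in seq_along(li)) {
        l <- li[k]; r <- ri[k]
        if (match_l[l] != r) {        # forward residual edge l -> r
          if (dist_l[l] < INF) {
            nd <- dist_l[l] - w[k]
            if (nd < dist_r[r] - 1e-9) {
              dist_r[r] <- nd; pred_r[r] <- k; changed <- TRUE
            }
          }
        }
      }
      for (r in seq_len(nr)) {
        if (match_r[r] != 0L && dist_r[r] < INF) {  # backward r -> matched l
          l <- match_r[r]; k <- edge_of_l[l]
          nd <- dist_r[r] + w[k]
          if (nd < dist_l[l] - 1e-9) {
            dist_l[l] <- nd; changed <- TRUE
          }
        }
      }
    }
    free_r <- which(match_r == 0L & dist_r < INF)
    if (length(free_r) == 0L) break
    # closest free right node; ties -> smallest index (canonical order)
    r <- free_r[which.min(dist_r[free_r])]
    # augment along predecessor chain
    repeat {
      k <- pred_r[r]
      l <- li[k]
      old_r <- match_l[l]
      match_l[l] <- r; match_r[r] <- l; edge_of_l[l] <- k
      if (old_r == 0L) break
      r <- old_r
    }
  }
  match_l
}

# Resolve a one-to-one assignment over a bipartite edge list.
# left, right: character keys; w: positive numeric weights.
# mode: "max_cardinality" (exact), "greedy", or "strict" (drop components
# whose optimum is not unique).
# Returns data.frame(left, right, weight) of matched pairs.
bipartite_assign <- function(left, right, w, mode = "max_cardinality") {
  if (length(left) == 0L) {
    return(df(left = character(0), right = character(0), weight = numeric(0)))
  }
  ord <- order(left, right)
  left <- left[ord]; right <- right[ord]; w <- w[ord]

  if (mode == "greedy") {
    ord2 <- order(-w, left, right)
    used_l <- character(0); used_r <- character(0)
    keep <- logical(length(left))
    for (k in ord2) {
      if (!(left[k] %in% used_l) && !(right[k] %in% used_r)) {
        keep[k] <- TRUE
        used_l <- c(used_l, left[k]); used_r <- c(used_r, right[k])
      }
    }
    return(df(left = left[keep], right = right[keep], weight = w[keep]))
  }

  lefts <- unique(left); rights <- unique(right)
  li <- match(left, lefts); ri <- match(right, rights)

  # union-find over left (1..nl) and right (nl+1..nl+nr)
  nl <- length(lefts); nr <- length(rights)
  parent <- seq_len(nl + nr)
  for (k in seq_along(li)) {
    a <- .uf_find(parent, li[k]); b <- .uf_find(parent, nl + ri[k])
    if (a != b) parent[b] <- a
  }
  comp_of_edge <- vapply(seq_along(li),
                         function(k) .uf_find(parent, li[k]), integer(1))

  out <- list()
  for (cid in unique(comp_of_edge)) {
    sel <- which(comp_of_edge == cid)
    if (length(sel) == 1L) {
      k <- sel
      out[[length(out) + 1L]] <- df(left = lefts[li[k]],
                                    right = rights[ri[k]], weight = w[k])
      next
    }
    sub_l <- sort(unique(li[sel])); sub_r <- sort(unique(ri[sel]))
    cli <- match(li[sel], sub_l); cri <- match(ri[sel], sub_r)
    m <- .match_component(cli, cri, w[sel], sub_l, sub_r)
    matched <- which(m != 0L)
    if (mode == "strict" &&
        .component_ambiguous(cli, cri, w[sel], length(sub_l), length(sub_r))) {
      next  # drop whole ambiguous component
    }
    for (l in matched) {
      r <- m[l]
      k <- sel[which(cli == l & cri == r)[1]]
      out[[length(out) + 1L]] <- df(left = lefts[li[k]],
                                    right = rights[ri[k]], weight = w[k])
    }
  }
  res <- do.call(rbind, out) %||% df(left = character(0),
                                     right = character(0),
                                     weight = numeric(0))
  res <- res[order(res$left, res$right), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive matcher: enumerate all matchings by DFS over left nodes.
# Returns list(cardinality, weight, n_optimal). Exponential; used for small
# components (strict-mode ambiguity check) and as the independent oracle in
# tests lives separately in the test helpers.
.enumerate_matchings <- function(li, ri, w, nl, nr, cap = 200000L) {
  adj <- vector("list", nl)
  for (k in seq_along(li)) adj[[li[k]]] <- c(adj[[li[k]]], k)
  best <- c(card = -1, weight = -Inf)
  n_best <- 0L
  n_states <- 0L
  used_r <- rep(FALSE, nr)
  recurse <- function(l, card, weight) {
    n_states <<- n_states + 1L
    if (n_states > cap) stop("enumeration cap exceeded", call. = FALSE)
    if (l > nl) {
      if (card > best["card"] ||
          (card == best["card"] && weight > best["weight"] + 1e-9)) {
        best <<- c(card = card, weight = weight)
        n_best <<- 1L
      } else if (card == best["card"] &&
                 abs(weight - best["weight"]) <= 1e-9) {
        n_best <<- n_best + 1L
      }
      return(invisible(NULL))
    }
    recurse(l + 1L, card, weight)  # leave l unmatched
    for (k in adj[[l]]) {
      if (!used_r[ri[k]]) {
        used_r[ri[k]] <<- TRUE
        recurse(l + 1L, card + 1L, weight + w[k])
        used_r[ri[k]] <<- FALSE
      }
    }
    invisible(NULL)
  }
  recurse(1L, 0L, 0)
  list(cardinality = unname(best["card"]), weight = unname(best["weight"]),
       n_optimal = n_best)
}

# A component is ambiguous when more than one matching attains the optimal
# (cardinality, weight). Counted by enumeration; if the component is too
# large to enumerate it is treated as ambiguous (conservative).
.component_ambiguous <- function(li, ri, w, nl, nr) {
  res <- tryCatch(.enumerate_matchings(li, ri, w, nl, nr),
                  error = function(e) NULL)
  if (is.null(res)) return(TRUE)
  res$n_optimal > 1L
}
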