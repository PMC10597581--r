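#' Collapse aligned sequences into haplotypes
#'
#' Columns containing any `N` or `-` anywhere in the alignment are masked
#' network-wide (complete deletion) before comparison, so pairwise
#' distances are true Hamming distances on a common site set. Identical
#' masked sequences form one haplotype; haplotypes are ordered by
#' first-seen sample.
#'
#' @param alignment named character vector of equal-length sequences.
#' @return a `haplotypes` list: `seqs` (named character vector of masked
#'   haplotype sequences, names `H1`, `H2`, ...), `count`, `members`
#'   (list of sample ids), `masked_columns` (0-based masked column
#'   indices).
#' @export
collapse_haplotypes <- function(alignment) {
  if (!length(alignment)) stop("zero sequences")
  if (is.null(names(alignment))) {
    names(alignment) <- paste0("seq", seq_along(alignment))
  }
  m <- seq_matrix(toupper(alignment))
  bad <- which(colSums(m == "N" | m == "-") > 0L)
  keep <- setdiff(seq_len(ncol(m)), bad)
  masked <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  first <- !duplicated(masked)
  hap_seq <- masked[first]
  hap_id <- paste0("H", seq_along(hap_seq))
  grp <- match(masked, hap_seq)
  structure(
    list(
      seqs = setNames(unname(hap_seq), hap_id),
      count = as.integer(table(factor(grp, levels = seq_along(hap_seq)))),
      members = split(names(alignment), grp),
      masked_columns = bad - 1L
    ),
    class = "haplotypes"
  )
}

#' @export
print.haplotypes <- function(x, ...) {
  cat(sprintf(
    "haplotypes: %d haplotypes from %d sequences (%d columns masked)\n",
    length(x$seqs), sum(x$count), length(x$masked_columns)
  ))
  invisible(x)
}

#' Hamming distance matrix between sequences
#'
#' @param seqs character vector of equal-length sequences.
#' @return symmetric integer matrix.
#' @export
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- seq_matrix(seqs)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  rownames(d) <- colnames(d) <- names(seqs)
  d
}

## Union-of-MSTs edge set at each distance tier (Kruskal with all
## equal-weight edges that join components distinct at the tier start).
.msn_edges <- function(d) {
  n <- nrow(d)
  comp <- seq_len(n)
  edges <- list()
  tiers <- sort(unique(d[upper.tri(d)]))
  for (w in tiers) {
    if (length(unique(comp)) == 1L) break
    tier_comp <- comp # components before this tier
    added <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (d[i, j] == w && tier_comp[i] != tier_comp[j]) {
          edges[[length(edges) + 1L]] <- c(i, j, w)
          added <- TRUE
        }
      }
    }
    if (added) {
      ## merge: union all tier edges
      for (e in edges) {
        if (e[3] == w) {
          ci <- comp[e[1]]
          cj <- comp[e[2]]
          if (ci != cj) comp[comp == cj] <- ci
        }
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(from = integer(0), to = integer(0), weight = integer(0)))
  }
  e <- do.call(rbind, edges)
  data.frame(from = e[, 1], to = e[, 2], weight = e[, 3])
}

#' Minimum spanning network of haplotypes
#'
#' The union of all minimum spanning trees under Hamming distance: working
#' through distance tiers in ascending order, every edge of the current
#' tier that joins two components distinct at the start of the tier is
#' included, then components are merged.
#'
#' @param haps a [collapse_haplotypes()] result, or a named character
#'   vector of equal-length haplotype sequences.
#' @return a `haplotype_network` list: `nodes` (data frame: `node_id`,
#'   `type` observed/median, `count`, `sequence`), `edges` (data frame:
#'   `from`, `to`, `weight`).
#' @export
minimum_spanning_network <- function(haps) {
  seqs <- if (inherits(haps, "haplotypes")) haps$seqs else haps
  count <- if (inherits(haps, "haplotypes")) {
    haps$count
  } else {
    rep(1L, length(seqs))
  }
  if (length(seqs) < 2L) stop("need >= 2 haplotypes")
  d <- hamming_matrix(seqs)
  e <- .msn_edges(d)
  nodes <- data.frame(
    node_id = names(seqs), type = "observed", count = count,
    sequence = unname(seqs), stringsAsFactors = FALSE
  )
  structure(
    list(
      nodes = nodes,
      edges = data.frame(
        from = names(seqs)[e$from], to = names(seqs)[e$to],
        weight = e$weight, stringsAsFactors = FALSE
      )
    ),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "haplotype_network: %d nodes (%d median), %d edges, total cost %d\n",
    nrow(x$nodes), sum(x$nodes$type == "median"), nrow(x$edges),
    sum(x$edges$weight)
  ))
  invisible(x)
}

## Coordinate-wise strict-majority median of three sequences, or NA when
## any column has three distinct bases (that triple contributes no vector).
.triple_median <- function(a, b, c) {
  x <- strsplit(c(a, b, c), "", fixed = TRUE)
  out <- character(length(x[[1]]))
  for (j in seq_along(out)) {
    col <- c(x[[1]][j], x[[2]][j], x[[3]][j])
    tab <- table(col)
    if (max(tab) == 1L) {
      return(NA_character_)
    }
    out[j] <- names(tab)[which.max(tab)]
  }
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Iteratively builds the minimum spanning network over the current node
#' set, inspects every triple of mutually linked nodes, and adds each
#' triple's coordinate-wise strict-majority median vector as a new
#' (inferred) node; repeats until no new vectors appear. With
#' `epsilon > 0`, links up to `epsilon` mutation steps costlier than the
#' MSN tier are also considered feasible when forming triples. Finally,
#' median vectors that are not on any shortest path between observed
#' haplotypes, or have degree < 3, are pruned.
#'
#' @param haps a [collapse_haplotypes()] result or named character vector.
#' @param epsilon feasible-link cost slack (default 0, the usual default).
#' @param max_iter iteration guard; exceeding it is an error carrying the
#'   partial network in `condition$partial`.
#' @return a `haplotype_network` with observed and median nodes.
#' @export
median_joining <- function(haps, epsilon = 0, max_iter = 50L) {
  seqs <- if (inherits(haps, "haplotypes")) haps$seqs else haps
  count <- if (inherits(haps, "haplotypes")) {
    haps$count
  } else {
    rep(1L, length(seqs))
  }
  if (length(seqs) < 2L) stop("need >= 2 haplotypes")
  observed <- names(seqs)
  all_seqs <- seqs
  n_median <- 0L

  feasible_links <- function(d, epsilon) {
    e <- .msn_edges(d)
    if (epsilon > 0) {
      extra <- which(d <= max(e$weight) + epsilon & upper.tri(d), arr.ind = TRUE)
      have <- paste(e$from, e$to)
      for (r in seq_len(nrow(extra))) {
        i <- extra[r, 1]
        j <- extra[r, 2]
        if (!paste(i, j) %in% have) {
          e <- rbind(e, data.frame(from = i, to = j, weight = d[i, j]))
        }
      }
    }
    e
  }

  for (iter in seq_len(max_iter + 1L)) {
    if (iter > max_iter) {
      cond <- structure(
        class = c("mj_non_convergence", "error", "condition"),
        list(
          message = "median-joining did not converge", call = sys.call(-1),
          partial = .finalize_network(all_seqs, observed, count, epsilon)
        )
      )
      stop(cond)
    }
    d <- hamming_matrix(all_seqs)
    e <- feasible_links(d, epsilon)
    adj <- matrix(FALSE, length(all_seqs), length(all_seqs))
    adj[cbind(e$from, e$to)] <- TRUE
    adj <- adj | t(adj)
    new_seqs <- character(0)
    nn <- length(all_seqs)
    for (i in seq_len(nn)) {
      js <- which(adj[i, ] & seq_len(nn) > i)
      for (j in js) {
        ks <- which(adj[i, ] & adj[j, ] & seq_len(nn) > j)
        for (k in ks) {
          med <- .triple_median(all_seqs[i], all_seqs[j], all_seqs[k])
          if (!is.na(med) && !med %in% all_seqs && !med %in% new_seqs) {
            new_seqs <- c(new_seqs, med)
          }
        }
      }
    }
    if (!length(new_seqs)) break
    ids <- paste0("M", n_median + seq_along(new_seqs))
    n_median <- n_median + length(new_seqs)
    all_seqs <- c(all_seqs, setNames(new_seqs, ids))
  }
  .finalize_network(all_seqs, observed, count, epsilon)
}

## Rebuild the MSN over a node set and prune median vectors that are not
## on a shortest path between two observed nodes or have degree < 3.
.finalize_network <- function(all_seqs, observed, count, epsilon) {
  repeat {
    d <- hamming_matrix(all_seqs)
    e <- .msn_edges(d)
    ids <- names(all_seqs)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ids[e$from], to = ids[e$to], weight = e$weight),
      directed = FALSE, vertices = ids
    )
    medians <- setdiff(ids, observed)
    if (!length(medians)) break
    dd <- igraph::distances(g, weights = igraph::E(g)$weight)
    deg <- igraph::degree(g)
    drop <- character(0)
    for (m in medians) {
      on_path <- FALSE
      for (a in observed) {
        for (b in observed) {
          if (a < b &&
            isTRUE(all.equal(dd[a, m] + dd[m, b], dd[a, b]))) {
            on_path <- TRUE
            break
          }
        }
        if (on_path) break
      }
      if (!on_path || deg[m] < 3L) drop <- c(drop, m)
    }
    if (!length(drop)) break
    all_seqs <- all_seqs[!names(all_seqs) %in% drop]
  }
  nodes <- data.frame(
    node_id = names(all_seqs),
    type = ifelse(names(all_seqs) %in% observed, "observed", "median"),
    count = c(count, rep(0L, length(all_seqs) - length(count)))[
      seq_along(all_seqs)
    ],
    sequence = unname(all_seqs),
    stringsAsFactors = FALSE
  )
  nodes$count[nodes$type == "median"] <- 0L
  structure(
    list(
      nodes = nodes,
      edges = data.frame(
        from = names(all_seqs)[e$from], to = names(all_seqs)[e$to],
        weight = e$weight, stringsAsFactors = FALSE
      )
    ),
    class = "haplotype_network"
  )
}

#' Write a haplotype network to TSV edge/node tables
#'
#' @param network a `haplotype_network`.
#' @param edges_file,nodes_file output paths.
#' @param haps optional [collapse_haplotypes()] result supplying member
#'   sample ids.
#' @return invisibly, the file paths.
#' @export
write_network <- function(network, edges_file, nodes_file, haps = NULL) {
  write.table(network$edges, edges_file,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  nodes <- network$nodes
  if (!is.null(haps)) {
    mem <- vapply(haps$members, paste, "", collapse = ",")
    nodes$members <- c(mem, rep("", nrow(nodes) - length(mem)))[
      seq_len(nrow(nodes))
    ]
    nodes$members[nodes$type == "median"] <- ""
  }
  write.table(nodes, nodes_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges_file, nodes_file))
}

#' Write a haplotype network in GML format
#'
#' @param network a `haplotype_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gml <- function(network, file) {
  g <- igraph::graph_from_data_frame(network$edges,
    directed = FALSE,
    vertices = network$nodes
  )
  igraph::write_graph(g, file, format = "gml")
  invisible(file)
}
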