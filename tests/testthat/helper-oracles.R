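## Independent reference implementations ("oracles") used to validate the
## package's optimised code paths. Deliberately written as plain per-element
## loops, sharing no code with R/.

## --- trimming oracle: position-by-position scanner ------------------------
oracle_trim <- function(q, cfg) {
  for (step in cfg$step_order) {
    n <- length(q)
    if (step == "MINLEN") {
      if (n < cfg$min_len) {
        return(NULL)
      }
    } else if (step == "AVGQUAL") {
      if (n == 0L || sum(q) / n < cfg$min_avg_q) {
        return(NULL)
      }
    } else if (step == "LEADING") {
      while (length(q) > 0L && q[1] < cfg$leading_q) q <- q[-1]
      if (!length(q)) {
        return(NULL)
      }
    } else if (step == "TRAILING") {
      while (length(q) > 0L && q[length(q)] < cfg$trailing_q) {
        q <- q[-length(q)]
      }
      if (!length(q)) {
        return(NULL)
      }
    } else if (step == "SLIDINGWINDOW") {
      n <- length(q)
      if (n >= cfg$window_len) {
        cut <- NA
        for (i in 1:(n - cfg$window_len + 1L)) {
          if (mean(q[i:(i + cfg$window_len - 1L)]) < cfg$window_q) {
            cut <- i - 1L
            break
          }
        }
        if (!is.na(cut)) {
          if (cut == 0L) {
            return(NULL)
          }
          q <- q[1:cut]
        }
      }
    }
  }
  q
}

## --- diagnostic-site oracle: exhaustive per-column scan --------------------
oracle_fixed_sites <- function(panel, max_missing_frac = 0.1) {
  seqs <- lapply(panel$seqs, function(s) strsplit(s, "")[[1]])
  clades <- sort(unique(panel$labels$clade))
  L <- length(seqs[[1]])
  out <- integer(0)
  for (col in seq_len(L)) {
    chars <- vapply(seqs, `[`, "", col)
    miss <- chars %in% c("N", "-")
    if (mean(miss) > max_missing_frac) next
    clade_base <- character(0)
    mono <- TRUE
    for (cl in clades) {
      b <- unique(chars[panel$labels$clade == cl & !miss])
      if (length(b) > 1L) {
        mono <- FALSE
        break
      }
      if (length(b) == 1L) clade_base <- c(clade_base, b)
    }
    if (mono && length(unique(clade_base)) >= 2L) out <- c(out, col - 1L)
  }
  out
}

## --- pileup oracle: per-read per-column recount ----------------------------
oracle_pileup <- function(mapped, L) {
  counts <- matrix(0L, 5L, L, dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (i in seq_len(nrow(mapped))) {
    ops <- regmatches(
      mapped$cigar[i],
      gregexpr("[0-9]+[MID]", mapped$cigar[i])
    )[[1]]
    rpos <- mapped$start[i]
    qpos <- 1L
    chars <- strsplit(mapped$seq[i], "")[[1]]
    for (op in ops) {
      n <- as.integer(sub("[MID]", "", op))
      kind <- substr(op, nchar(op), nchar(op))
      if (kind == "M") {
        for (t in 1:n) {
          b <- chars[qpos + t - 1L]
          if (b %in% c("A", "C", "G", "T")) {
            col <- rpos + t - 1L
            counts[b, col %% L + 1L] <- counts[b, col %% L + 1L] + 1L
          }
        }
        rpos <- rpos + n
        qpos <- qpos + n
      } else if (kind == "D") {
        for (t in 1:n) {
          counts["-", (rpos + t - 1L) %% L + 1L] <-
            counts["-", (rpos + t - 1L) %% L + 1L] + 1L
        }
        rpos <- rpos + n
      } else {
        qpos <- qpos + n
      }
    }
  }
  counts
}

## --- MSN oracle: enumerate all spanning trees (n <= 7) ---------------------
oracle_msn_edges <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L, n <= 7L)
  d <- matrix(0L, n, n)
  sp <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(sp[[i]] != sp[[j]])
    }
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best_w <- Inf
  best_trees <- list()
  for (comb in utils::combn(m, n - 1L, simplify = FALSE)) {
    sel <- pairs[comb, , drop = FALSE]
    ## connectivity check by repeated expansion
    comp <- seq_len(n)
    for (r in seq_len(nrow(sel))) {
      a <- comp[sel[r, 1]]
      b <- comp[sel[r, 2]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) != 1L) next
    w <- sum(d[sel])
    if (w < best_w) {
      best_w <- w
      best_trees <- list(sel)
    } else if (w == best_w) {
      best_trees <- c(best_trees, list(sel))
    }
  }
  edges <- unique(do.call(rbind, best_trees))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  data.frame(
    from = names(seqs)[edges[, 1]], to = names(seqs)[edges[, 2]],
    weight = d[edges]
  )
}

## --- haplotype partition oracle: pairwise equality after masking -----------
oracle_hap_partition <- function(alignment) {
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  bad <- apply(m, 2L, function(col) any(col %in% c("N", "-")))
  m <- m[, !bad, drop = FALSE]
  n <- nrow(m)
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[i] <- g
      if (i < n) {
        for (j in (i + 1L):n) {
          if (grp[j] == 0L && all(m[i, ] == m[j, ])) grp[j] <- g
        }
      }
    }
  }
  grp
}
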