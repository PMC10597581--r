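#' Construct a clade panel
#'
#' An aligned set of mitogenome sequences (equal length, over
#' `A/C/G/T/N/-`) with one clade label per sample plus provenance metadata
#' — the in-memory form of an aligned multi-FASTA with a TSV sidecar.
#'
#' @param seqs named character vector of aligned sequences.
#' @param labels data frame with columns `sample_id`, `clade` and
#'   optionally `species`, `latitude`, `longitude`; one row per sequence.
#' @return a `clade_panel` list.
#' @export
clade_panel <- function(seqs, labels) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("panel sequences must be aligned (equal length)")
  }
  if (!all(c("sample_id", "clade") %in% names(labels))) {
    stop("labels must have sample_id and clade columns")
  }
  labels <- labels[match(names(seqs), labels$sample_id), , drop = FALSE]
  if (anyNA(labels$clade)) stop("every sequence needs a clade label")
  if (length(unique(labels$clade)) < 2L) stop("panel needs >= 2 clades")
  rownames(labels) <- NULL
  structure(
    list(seqs = toupper(seqs), labels = labels),
    class = "clade_panel"
  )
}

#' @export
print.clade_panel <- function(x, ...) {
  cat(sprintf(
    "clade_panel: %d samples, %d clades, alignment length %d\n",
    length(x$seqs), length(unique(x$labels$clade)), nchar(x$seqs[1])
  ))
  invisible(x)
}

#' Read a clade panel from aligned FASTA + TSV sidecar
#'
#' @param fasta path to the aligned multi-FASTA.
#' @param tsv path to the sidecar (columns `sample_id`, `clade`, ...).
#' @return a [clade_panel()].
#' @export
read_clade_panel <- function(fasta, tsv) {
  seqs <- read_fasta(fasta)
  labels <- read.delim(tsv, stringsAsFactors = FALSE)
  clade_panel(seqs, labels)
}

#' Write a clade panel to aligned FASTA + TSV sidecar
#'
#' @param panel a [clade_panel()].
#' @param fasta,tsv output paths.
#' @return invisibly, `c(fasta, tsv)`.
#' @export
write_clade_panel <- function(panel, fasta, tsv) {
  write_fasta(panel$seqs, fasta)
  write.table(panel$labels, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, tsv))
}

## Panel columns as an n x L character matrix, plus missing mask.
.panel_matrix <- function(panel) {
  m <- seq_matrix(panel$seqs)
  list(m = m, miss = m == "N" | m == "-")
}

## Per-clade monomorphism over all columns: returns list(base = clade x L
## character matrix of the clade base where monomorphic (NA otherwise;
## all-missing columns give NA with ok = TRUE), ok = clade x L logical,
## TRUE when the clade is monomorphic (or all-missing) at the column.
.clade_bases <- function(m, miss, clades, clade_of) {
  L <- ncol(m)
  base <- matrix(NA_character_, length(clades), L,
    dimnames = list(clades, NULL)
  )
  ok <- matrix(TRUE, length(clades), L, dimnames = list(clades, NULL))
  for (ci in seq_along(clades)) {
    rows <- which(clade_of == clades[ci])
    pres <- vapply(DNA_BASES, function(b) {
      colSums(m[rows, , drop = FALSE] == b & !miss[rows, , drop = FALSE]) > 0L
    }, logical(L))
    if (L == 1L) pres <- matrix(pres, nrow = 1L)
    ndistinct <- rowSums(pres)
    ok[ci, ] <- ndistinct <= 1L
    hit <- ndistinct == 1L
    base[ci, hit] <- DNA_BASES[max.col(pres[hit, , drop = FALSE],
      ties.method = "first"
    )]
  }
  list(base = base, ok = ok)
}

#' Discover inter-clade fixed differences
#'
#' Finds alignment columns at which every clade is monomorphic (ignoring
#' `N`/`-`; a clade with only missing data at a column contributes no
#' constraint) and at least two clades carry different bases. Columns with
#' more than `max_missing_frac` missing characters are excluded.
#'
#' @param panel a [clade_panel()].
#' @param max_missing_frac maximum fraction of `N`/`-` per column
#'   (default 0.1).
#' @param focal_clade optional clade whose base becomes `focal_base`
#'   (the base read agreement is later measured against).
#' @return a `diagnostic_sites` data frame: `column` (0-based), `kind`,
#'   `focal_base`, and one `base_<clade>` column per clade; ascending by
#'   `column`.
#' @export
find_inter_clade_fixed_sites <- function(panel, max_missing_frac = 0.1,
                                         focal_clade = NULL) {
  pm <- .panel_matrix(panel)
  clade_of <- panel$labels$clade
  clades <- sort(unique(clade_of))
  if (length(clades) < 2L) stop("panel needs >= 2 clades")
  cb <- .clade_bases(pm$m, pm$miss, clades, clade_of)
  missing_ok <- colMeans(pm$miss) <= max_missing_frac
  all_mono <- colSums(!cb$ok) == 0L
  ndiff <- apply(cb$base, 2L, function(x) length(unique(x[!is.na(x)])))
  sel <- which(missing_ok & all_mono & ndiff >= 2L)
  sites <- data.frame(
    column = sel - 1L,
    kind = rep("inter_clade_fixed", length(sel)),
    focal_base = if (is.null(focal_clade)) {
      rep(NA_character_, length(sel))
    } else {
      cb$base[focal_clade, sel]
    },
    stringsAsFactors = FALSE
  )
  for (cn in clades) sites[[paste0("base_", cn)]] <- cb$base[cn, sel]
  class(sites) <- c("diagnostic_sites", "data.frame")
  sites
}

#' Sites fixed in a focal clade but divergent in a query consensus
#'
#' Finds columns where the focal clade is monomorphic (ignoring `N`/`-`)
#' and the query consensus carries a different, determined base. The
#' query's base becomes `focal_base`: read agreement at these sites then
#' measures support for the query's private variants (high agreement =
#' authentic variant, low = contamination or error).
#'
#' @param panel a [clade_panel()].
#' @param focal_clade clade label present in the panel.
#' @param query query consensus aligned to panel coordinates (string).
#' @param exclude_sample optional sample id to drop from the focal clade
#'   (the query itself, if it is a panel member).
#' @return a `diagnostic_sites` data frame with `column` (0-based), `kind`,
#'   `clade_base` and `focal_base` (= query base).
#' @export
find_clade_fixed_query_divergent_sites <- function(panel, focal_clade, query,
                                                   exclude_sample = NULL) {
  if (!focal_clade %in% panel$labels$clade) {
    stop("focal clade absent from panel")
  }
  keep <- panel$labels$sample_id != (exclude_sample %||% "")
  sub <- panel
  sub$seqs <- panel$seqs[keep]
  sub$labels <- panel$labels[keep, , drop = FALSE]
  pm <- .panel_matrix(sub)
  rows <- which(sub$labels$clade == focal_clade)
  if (!length(rows)) stop("focal clade absent from panel")
  if (nchar(query) != ncol(pm$m)) {
    stop("query must be aligned to panel coordinates")
  }
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  cb <- .clade_bases(
    pm$m[rows, , drop = FALSE], pm$miss[rows, , drop = FALSE],
    focal_clade, rep(focal_clade, length(rows))
  )
  clade_base <- cb$base[1L, ]
  sel <- which(
    !is.na(clade_base) & cb$ok[1L, ] & q %in% DNA_BASES & q != clade_base
  )
  sites <- data.frame(
    column = sel - 1L,
    kind = rep("clade_fixed_query_divergent", length(sel)),
    clade_base = clade_base[sel],
    focal_base = q[sel],
    stringsAsFactors = FALSE
  )
  class(sites) <- c("diagnostic_sites", "data.frame")
  sites
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map panel columns to ungapped reference coordinates
#'
#' Panel columns where the named reference row carries a gap have no
#' reference coordinate and map to `NA`.
#'
#' @param panel a [clade_panel()].
#' @param ref_sample sample id of the reference row.
#' @return integer vector, length = alignment length: 0-based reference
#'   position of each column, or `NA` for reference-gap columns.
#' @export
panel_to_ref_coords <- function(panel, ref_sample) {
  s <- panel$seqs[[ref_sample]]
  if (is.null(s)) stop("reference sample not in panel")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  isgap <- chars == "-"
  pos <- cumsum(!isgap) - 1L
  pos[isgap] <- NA_integer_
  pos
}

#' Per-site read agreement at diagnostic sites
#'
#' For each diagnostic site, the agreement fraction is the share of reads
#' covering the site that carry `focal_base`. The median and the
#' interquartile range (Q3 - Q1, linear interpolation) are computed over
#' covered sites only; zero-coverage sites are excluded and reported.
#'
#' @param pileup a [make_pileup()] result on the mapping reference.
#' @param sites a `diagnostic_sites` data frame with non-`NA` `focal_base`.
#' @param coords optional integer vector mapping panel columns to 0-based
#'   reference positions (see [panel_to_ref_coords()]); by default panel
#'   columns are taken as reference positions (valid for gap-free
#'   references).
#' @return an `agreement_stats` list: `per_site` (site table with base
#'   tallies and agreement), `median`, `iqr`, `n_sites`, `n_zero_coverage`,
#'   `n_ref_gap`.
#' @export
site_agreement <- function(pileup, sites, coords = NULL) {
  if (anyNA(sites$focal_base)) {
    stop("sites must carry a focal_base (set focal_clade or use query-divergent sites)")
  }
  pos <- if (is.null(coords)) sites$column else coords[sites$column + 1L]
  ref_gap <- is.na(pos)
  sites <- sites[!ref_gap, , drop = FALSE]
  pos <- pos[!ref_gap]
  depth <- pileup$depth[pos + 1L]
  agree_n <- pileup$counts[cbind(match(sites$focal_base, rownames(pileup$counts)), pos + 1L)]
  covered <- depth > 0L
  if (!any(covered)) stop("all diagnostic sites uncovered")
  per_site <- data.frame(
    column = sites$column,
    position = pos,
    focal_base = sites$focal_base,
    A = pileup$counts["A", pos + 1L],
    C = pileup$counts["C", pos + 1L],
    G = pileup$counts["G", pos + 1L],
    T = pileup$counts["T", pos + 1L],
    depth = depth,
    agreement = ifelse(covered, agree_n / depth, NA_real_)
  )
  a <- per_site$agreement[covered]
  q <- quantile(a, c(0.25, 0.75), type = 7, names = FALSE)
  structure(
    list(
      per_site = per_site,
      median = median(a),
      iqr = q[2] - q[1],
      n_sites = sum(covered),
      n_zero_coverage = sum(!covered),
      n_ref_gap = sum(ref_gap)
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "agreement_stats: median %.1f%% (IQR %.1f%%) over %d sites (%d uncovered)\n",
    100 * x$median, 100 * x$iqr, x$n_sites, x$n_zero_coverage
  ))
  invisible(x)
}

#' p-distance between two aligned sequences
#'
#' Proportion of differing sites under pairwise deletion of `N`/`-`.
#'
#' @param a,b aligned sequences (equal length strings).
#' @return proportion in `[0, 1]`, or `NA` if no comparable sites.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned")
  use <- x %in% DNA_BASES & y %in% DNA_BASES
  if (!any(use)) {
    return(NA_real_)
  }
  mean(x[use] != y[use])
}

#' Assign a query consensus to a clade by diagnostic sites
#'
#' At every inter-clade fixed site where the query is determined, each
#' clade whose base equals the query base receives a vote. The clade with
#' strictly the most votes wins; ties are broken by the smallest
#' p-distance between the query and the clade consensus.
#'
#' @param query query consensus aligned to panel coordinates (string).
#' @param panel a [clade_panel()].
#' @param sites optional precomputed [find_inter_clade_fixed_sites()]
#'   result.
#' @param max_missing_frac passed to site discovery when `sites` is `NULL`.
#' @return a `clade_assignment` list: `assigned`, `votes` (named vector),
#'   `p_dist` (named vector), `n_usable_sites`, `rule`
#'   (`"votes"` or `"votes+pdist"`).
#' @export
assign_clade <- function(query, panel, sites = NULL, max_missing_frac = 0.1) {
  if (is.null(sites)) {
    sites <- find_inter_clade_fixed_sites(panel, max_missing_frac)
  }
  clades <- sort(unique(panel$labels$clade))
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  if (length(q) != nchar(panel$seqs[1])) {
    stop("query must be aligned to panel coordinates")
  }
  qb <- q[sites$column + 1L]
  usable <- qb %in% DNA_BASES
  if (!any(usable)) stop("unassignable: zero usable diagnostic sites")
  votes <- setNames(integer(length(clades)), clades)
  for (cn in clades) {
    cb <- sites[[paste0("base_", cn)]]
    votes[cn] <- sum(usable & !is.na(cb) & cb == qb)
  }
  ## clade consensus sequences for the tie-break
  cons <- vapply(clades, function(cn) {
    rows <- panel$labels$clade == cn
    m <- seq_matrix(panel$seqs[rows])
    paste(apply(m, 2L, function(col) {
      col <- col[col %in% DNA_BASES]
      if (!length(col)) {
        return("N")
      }
      tab <- table(col)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) top else "N"
    }), collapse = "")
  }, character(1))
  p_dist <- vapply(cons, function(s) p_distance(query, s), numeric(1))
  top <- votes == max(votes)
  if (sum(top) == 1L) {
    assigned <- names(votes)[top]
    rule <- "votes"
  } else {
    cand <- names(votes)[top]
    assigned <- cand[which.min(p_dist[cand])]
    rule <- "votes+pdist"
  }
  structure(
    list(
      assigned = assigned, votes = votes, p_dist = p_dist,
      n_usable_sites = sum(usable), rule = rule
    ),
    class = "clade_assignment"
  )
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf(
    "clade_assignment: %s (%s; votes %s)\n", x$assigned, x$rule,
    paste(names(x$votes), x$votes, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Extract a column interval from an alignment
#'
#' @param alignment named character vector of aligned sequences, or a
#'   [clade_panel()].
#' @param interval 0-based half-open `c(start, end)` column interval.
#' @return object of the same kind, sliced to the interval.
#' @export
extract_region <- function(alignment, interval) {
  start <- interval[1]
  end <- interval[2]
  if (end <= start) stop("empty interval")
  slice <- function(s) substring(s, start + 1L, end)
  if (inherits(alignment, "clade_panel")) {
    if (end > nchar(alignment$seqs[1])) stop("interval outside alignment")
    alignment$seqs <- setNames(slice(alignment$seqs), names(alignment$seqs))
    alignment
  } else {
    if (end > nchar(alignment[1])) stop("interval outside alignment")
    setNames(slice(alignment), names(alignment))
  }
}

#' Remove sequences with too much missing data
#'
#' Drops sequences whose fraction of `N`/`-` characters exceeds
#' `max_frac` (strictly greater than).
#'
#' @param alignment named character vector of aligned sequences.
#' @param max_frac missing-data threshold (default 0.10).
#' @return the filtered alignment, with attribute `"removed"` naming the
#'   dropped sequences and their missing fractions.
#' @export
filter_missing <- function(alignment, max_frac = 0.10) {
  frac <- vapply(alignment, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(chars == "N" | chars == "-")
  }, numeric(1))
  drop <- frac > max_frac
  out <- alignment[!drop]
  attr(out, "removed") <- data.frame(
    sample_id = names(alignment)[drop],
    missing_fraction = unname(frac[drop])
  )
  out
}
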