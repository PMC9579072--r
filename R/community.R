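#' Build the station-visit community biomass matrix
#'
#' Averages replicate grabs to one row per station visit (station x
#' period) on the ln(X+1) scale and drops rare groups. The default
#' (`transform_first = TRUE`) transforms each replicate then averages;
#' the alternative averages raw biomass then transforms. Hotspot rows
#' are excluded by default (the ordination describes the detailed grid).
#'
#' @param table A `survey_table`.
#' @param min_prevalence Drop groups present (value > 0) at fewer than
#'   this fraction of station visits; in `[0, 1)`, default 0.05.
#' @param transform_first Transform-then-average (default) or
#'   average-then-transform.
#' @param include_hotspots Keep hotspot rows as additional station
#'   visits; default `FALSE`.
#' @return A `community_matrix`: list with `values` (matrix, station
#'   visits x groups), `meta` (station_id, period, zone, sediment, line,
#'   depth class), `transform`, and `dropped` (excluded groups).
#' @export
build_community_matrix <- function(table, min_prevalence = 0.05,
                                   transform_first = TRUE,
                                   include_hotspots = FALSE) {
  if (min_prevalence < 0 || min_prevalence >= 1) {
    stop("`min_prevalence` must be in [0, 1)", call. = FALSE)
  }
  sub <- if (include_hotspots) table else table[table$design == "grid", ]
  if (!nrow(sub)) stop("no rows to build community matrix from", call. = FALSE)
  unit <- paste(sub$station_id, sub$period, sep = "@")
  groups <- unique(sub$taxon_group)
  if (transform_first) {
    v <- tapply(transform_biomass(sub$biomass_wet_g_per_m2),
                list(unit, sub$taxon_group), mean)
  } else {
    v <- log1p(tapply(sub$biomass_wet_g_per_m2,
                      list(unit, sub$taxon_group), mean))
  }
  v <- v[, intersect(groups, colnames(v)), drop = FALSE]
  if (anyNA(v)) stop("unbalanced table: some station visits lack groups",
                     call. = FALSE)
  first <- !duplicated(unit)
  meta <- data.frame(station_id = sub$station_id[first],
                     period = sub$period[first],
                     zone = sub$zone[first],
                     sediment = sub$sediment[first],
                     line = sub$line[first],
                     row.names = unit[first])
  meta <- meta[rownames(v), ]
  meta$depth <- factor(meta$line)
  prev <- colMeans(v > 0)
  keep <- prev >= min_prevalence
  dropped <- colnames(v)[!keep]
  v <- v[, keep, drop = FALSE]
  if (!ncol(v)) stop("all groups excluded as rare", call. = FALSE)
  structure(list(values = v, meta = meta,
                 transform = if (transform_first) "transform-then-average"
                             else "average-then-transform",
                 min_prevalence = min_prevalence, dropped = dropped),
            class = "community_matrix")
}

.as_values <- function(M) {
  if (inherits(M, "community_matrix")) M$values else as.matrix(M)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})} on
#' the (non-negative) community matrix. Pairs of all-zero rows are 0/0
#' under the formula and are set to 0 with a warning.
#'
#' @param M A `community_matrix` or non-negative numeric matrix.
#' @return Square symmetric matrix of class `dissimilarity_matrix`,
#'   entries in `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(M) {
  x <- .as_values(M)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative values",
                       call. = FALSE)
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (anyNA(d)) {
    warning("all-zero row pair(s): dissimilarity set to 0", call. = FALSE)
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  stopifnot(isTRUE(all.equal(d, t(d))), all(d >= 0 & d <= 1 + 1e-12))
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (monotone regression, multiple random starts,
#' convergence by Procrustes agreement between starts), delegated to
#' [vegan::metaMDS()]. Coordinates are centered at the origin; the
#' configuration is reproducible by `seed`.
#'
#' @param D A `dissimilarity_matrix` (or `dist`).
#' @param k Embedding dimension; default 2.
#' @param n_starts Random starts; default 20.
#' @param max_iter Iterations per start; default 200.
#' @param seed Integer seed.
#' @return An `ordination` list: `points` (n x k), `stress` (in `[0,1]`),
#'   `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 200, seed = 1L) {
  stopifnot(k >= 1, n_starts >= 1)
  d <- stats::as.dist(D)
  set.seed(as.integer(seed))
  m <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                      maxit = max_iter, trace = 0, autotransform = FALSE,
                      wascores = FALSE)
  pts <- scale(m$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  colnames(pts) <- paste0("NMDS", seq_len(k))
  conv <- isTRUE(m$converged) || (is.numeric(m$converged) && m$converged > 0)
  if (!conv) warning("NMDS did not converge; best configuration returned",
                     call. = FALSE)
  structure(list(points = pts, stress = m$stress, converged = conv,
                 n_starts = n_starts, seed = as.integer(seed)),
            class = "ordination")
}

#' Group centroids with t-based confidence intervals
#'
#' Per-axis group means and `level` confidence half-widths
#' (\eqn{t_{n-1} \cdot s/\sqrt{n}}) of ordination coordinates, the
#' numeric version of a centroid-and-CI inset plot. Singleton groups get
#' `NA` half-widths and are flagged.
#'
#' @param ord An `ordination` (or coordinate matrix).
#' @param grouping Factor of group labels (e.g. period x zone), one per
#'   ordination point.
#' @param level Confidence level; default 0.95.
#' @return Data frame: group, n, per-axis centroid and CI half-width,
#'   `ci_defined` flag.
#' @export
centroids_ci <- function(ord, grouping, level = 0.95) {
  pts <- if (inherits(ord, "ordination")) ord$points else as.matrix(ord)
  grouping <- factor(grouping)
  stopifnot(length(grouping) == nrow(pts))
  out <- lapply(levels(grouping), function(g) {
    p <- pts[grouping == g, , drop = FALSE]
    n <- nrow(p)
    ctr <- colMeans(p)
    if (n >= 2L) {
      hw <- stats::qt(1 - (1 - level) / 2, n - 1) *
        apply(p, 2, stats::sd) / sqrt(n)
    } else {
      hw <- rep(NA_real_, ncol(p))
    }
    d <- data.frame(group = g, n = n)
    for (j in seq_len(ncol(p))) {
      d[[paste0("centroid", j)]] <- ctr[j]
      d[[paste0("halfwidth", j)]] <- hw[j]
    }
    d$ci_defined <- n >= 2L
    d
  })
  do.call(rbind, out)
}

# Gower-centered inner-product matrix of a dissimilarity matrix.
.gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

# Orthonormal basis of the column space of X.
.col_basis <- function(X) {
  q <- qr(X)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

# Sequential hat-difference matrices for a list of terms.
.term_hats <- function(terms, data) {
  n <- nrow(data)
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  out <- list()
  for (j in seq_along(terms)) {
    f <- stats::reformulate(terms[seq_len(j)])
    X <- stats::model.matrix(f, data)
    Q <- .col_basis(X)
    H <- tcrossprod(Q)
    out[[terms[j]]] <- list(Hd = H - H_prev, df = ncol(Q) - rank_prev)
    H_prev <- H
    rank_prev <- ncol(Q)
  }
  list(terms = out, H_full = H_prev, rank_full = rank_prev)
}

#' Permutational multivariate analysis of variance (NPMANOVA)
#'
#' Partitions the Bray-Curtis dissimilarity matrix of a community matrix
#' by the design factors using the Gower-centered inner-product
#' decomposition with sequential (entry-order) sums of squares. Each
#' term's pseudo-F uses the full-model residual; p-values come from free
#' (unrestricted) permutations of the rows:
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param M A `community_matrix` (factors are read from its `meta`), or
#'   a `dissimilarity_matrix` if `data` is supplied.
#' @param terms Character vector of model terms, fitted in this order;
#'   default `c("period", "zone", "sediment", "depth", "period:zone")`
#'   with depth entering as the two-level isobath factor.
#' @param n_perm Number of random permutations; default 9999.
#' @param seed Integer seed for the permutation stream.
#' @param permutations Optional explicit permutation matrix (one
#'   permutation per row). When given, the p-value is the exact
#'   proportion of the supplied set (include the identity for a closed
#'   test) with `F_perm >= F_obs`.
#' @param data Factor data frame, needed only when `M` is already a
#'   dissimilarity matrix.
#' @return An `npmanova` object: `aov_table` (term, df, SS, R2, pseudo_F,
#'   p), plus residual and total rows, `n_perm`, `seed`.
#' @export
npmanova <- function(M, terms = c("period", "zone", "sediment", "depth",
                                  "period:zone"),
                     n_perm = 9999, seed = 1L, permutations = NULL,
                     data = NULL) {
  if (inherits(M, "community_matrix")) {
    d <- bray_curtis(M)
    data <- M$meta
  } else {
    d <- as.matrix(M)
    if (is.null(data)) stop("`data` required when `M` is a matrix",
                            call. = FALSE)
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) data[[v]] <- factor(data[[v]])
  n <- nrow(d)
  G <- .gower_center(d)
  hats <- .term_hats(terms, data)
  SS_tot <- sum(diag(G))
  ss_of <- function(Gm) vapply(hats$terms, function(h) sum(h$Hd * Gm),
                               numeric(1))
  SS <- ss_of(G)
  df <- vapply(hats$terms, `[[`, numeric(1), "df")
  if (any(df == 0)) {
    stop("confounded term(s): ", paste(terms[df == 0], collapse = ", "),
         call. = FALSE)
  }
  df_res <- n - hats$rank_full
  if (df_res <= 0) stop("zero residual degrees of freedom", call. = FALSE)
  SS_res <- SS_tot - sum(SS)
  F_obs <- (SS / df) / (SS_res / df_res)

  perm_F <- function(p) {
    Gp <- G[p, p]
    SSp <- ss_of(Gp)
    (SSp / df) / ((SS_tot - sum(SSp)) / df_res)
  }
  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    stopifnot(ncol(permutations) == n)
    ge <- matrix(0, nrow(permutations), length(terms))
    for (i in seq_len(nrow(permutations))) {
      ge[i, ] <- perm_F(permutations[i, ]) >= F_obs - 1e-12
    }
    p_val <- colMeans(ge)
    n_perm <- nrow(permutations)
  } else {
    stopifnot(n_perm >= 99)
    set.seed(as.integer(seed))
    count <- numeric(length(terms))
    for (i in seq_len(n_perm)) {
      count <- count + (perm_F(sample.int(n)) >= F_obs - 1e-12)
    }
    p_val <- (1 + count) / (1 + n_perm)
  }

  aov_table <- data.frame(term = terms, df = df, SS = SS,
                          R2 = SS / SS_tot, pseudo_F = F_obs, p = p_val)
  rownames(aov_table) <- NULL
  structure(list(aov_table = aov_table,
                 residual = data.frame(df = df_res, SS = SS_res,
                                       R2 = SS_res / SS_tot),
                 total = data.frame(df = n - 1, SS = SS_tot),
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "npmanova")
}

#' Pairwise permutational comparisons with Holm adjustment
#'
#' Two-group permutational pseudo-F tests on every pair of groups
#' (default: the period x zone combinations), followed by the Holm
#' step-down adjustment at `alpha` -- the multiple-comparison companion
#' to [npmanova()].
#'
#' @param M A `community_matrix`.
#' @param grouping Factor of group labels per station visit; default
#'   `interaction(period, zone)` from the matrix metadata.
#' @param n_perm Permutations per pairwise test; default 999.
#' @param seed Integer seed.
#' @param alpha Family-wise level for the significance flag.
#' @return Data frame: group pair, group sizes, pseudo-F, raw and
#'   Holm-adjusted p, significance flag.
#' @export
pairwise_permutation <- function(M, grouping = NULL, n_perm = 999,
                                 seed = 1L, alpha = 0.05) {
  stopifnot(inherits(M, "community_matrix"))
  if (is.null(grouping)) {
    grouping <- interaction(M$meta$period, M$meta$zone, sep = "-")
  }
  grouping <- factor(grouping)
  stopifnot(length(grouping) == nrow(M$values))
  sizes <- table(grouping)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  d_full <- bray_curtis(M)
  pairs <- utils::combn(levels(grouping), 2)
  set.seed(as.integer(seed))
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    sel <- grouping %in% c(g1, g2)
    sub <- npmanova(d_full[sel, sel], terms = "g",
                    n_perm = n_perm, seed = sample.int(2^31 - 1, 1),
                    data = data.frame(g = droplevels(grouping[sel])))
    data.frame(group1 = g1, group2 = g2,
               n1 = sum(grouping == g1), n2 = sum(grouping == g2),
               pseudo_F = sub$aov_table$pseudo_F,
               p_raw = sub$aov_table$p)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_holm <= alpha
  out
}
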