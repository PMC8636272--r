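#' Shannon diversity index
#'
#' H = -sum p_i ln p_i over normalized abundances, zero entries skipped;
#' natural-log units, so 0 <= H <= ln(S).
#'
#' @param abundances non-negative vector with positive sum.
#' @return H in nats.
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0) || anyNA(abundances)) {
    abort_invalid("abundances must be non-negative")
  }
  if (sum(abundances) <= 0) abort_invalid("abundance vector sums to zero")
  p <- abundances / sum(abundances)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Time-bin or sample assemblage
#'
#' @param label bin or sample label.
#' @param taxa character vector of taxa present (may be empty for an
#'   explicit empty-bin placeholder).
#' @param abundance optional named abundances.
#' @return An object of class `assemblage`.
#' @export
assemblage <- function(label, taxa, abundance = NULL) {
  if (!is.null(abundance) && any(abundance < 0)) {
    abort_invalid("abundances must be non-negative")
  }
  structure(list(label = label, taxa = unique(as.character(taxa)),
                 abundance = abundance, empty = length(taxa) == 0L),
            class = "assemblage")
}

.as_taxa <- function(x) {
  if (inherits(x, "assemblage")) x$taxa else unique(as.character(x))
}

#' Beta-diversity (dissimilarity) between two assemblages
#'
#' Default is the incidence-based Sørensen dissimilarity
#' 1 - 2a/(2a + b + c) with a = shared taxa and b, c the taxa unique to each
#' side; Jaccard (incidence) and Bray-Curtis (abundance) are selectable.
#' Symmetric; 0 iff equal incidence sets; 1 for disjoint sets. Two empty
#' assemblages give NA (undefined) with a warning.
#'
#' @param A,B [assemblage()]s or character vectors of taxa (named abundance
#'   vectors for `method = "bray"`).
#' @param method "sorensen", "jaccard" or "bray".
#' @return Dissimilarity in \[0, 1\], or NA if undefined.
#' @export
beta_dissimilarity <- function(A, B, method = c("sorensen", "jaccard", "bray")) {
  method <- match.arg(method)
  if (method == "bray") {
    av <- if (inherits(A, "assemblage")) A$abundance else A
    bv <- if (inherits(B, "assemblage")) B$abundance else B
    if (is.null(av) || is.null(bv) || is.null(names(av)) || is.null(names(bv))) {
      abort_invalid("bray method needs named abundance vectors")
    }
    taxa <- union(names(av), names(bv))
    x <- stats::setNames(rep(0, length(taxa)), taxa)
    y <- x
    x[names(av)] <- av
    y[names(bv)] <- bv
    if (sum(x) + sum(y) == 0) {
      warning("both assemblages empty: dissimilarity undefined")
      return(NA_real_)
    }
    return(sum(abs(x - y)) / sum(x + y))
  }
  ta <- .as_taxa(A)
  tb <- .as_taxa(B)
  if (!length(ta) && !length(tb)) {
    warning("both assemblages empty: dissimilarity undefined")
    return(NA_real_)
  }
  a <- length(intersect(ta, tb))
  b <- length(setdiff(ta, tb))
  c <- length(setdiff(tb, ta))
  if (method == "sorensen") 1 - 2 * a / (2 * a + b + c) else 1 - a / (a + b + c)
}

#' Combine samples into fixed-width time-bin assemblages
#'
#' Half-open bins \[t, t + width) anchored at age 0: a genus is present in a
#' bin if present in any sample falling in the bin. Empty bins inside the
#' covered range are emitted as flagged placeholders so turnover series keep
#' their spacing. Pan-Arctic analyses conventionally use 2,000-year bins and
#' regional ones 5,000-year bins; `bin_width` is free.
#'
#' @param m a `count_matrix` (or `relative_abundance`).
#' @param ages named numeric vector, sample id -> age (years BP). Samples
#'   with missing age are excluded and logged in the `"excluded"` attribute.
#' @param bin_width bin width in years.
#' @param age_range optional (min, max) ages to cover; default the data range.
#' @return Ordered list of [assemblage()]s (oldest last), labels
#'   `"[t0,t1)"`.
#' @export
bin_assemblages <- function(m, ages, bin_width, age_range = NULL) {
  if (!is.numeric(bin_width) || bin_width <= 0) abort_invalid("`bin_width` must be > 0")
  mat <- if (inherits(m, "relative_abundance")) m$abundance else m$counts
  samples <- colnames(mat)
  age <- ages[samples]
  excluded <- samples[is.na(age)]
  keep <- !is.na(age)
  mat <- mat[, keep, drop = FALSE]
  age <- age[keep]
  if (!length(age)) abort_invalid("no samples with finite ages")
  rng <- age_range %||% range(age)
  lo <- bin_width * floor(rng[1] / bin_width)
  hi <- bin_width * ceiling((rng[2] + 1e-9) / bin_width)
  starts <- seq(lo, hi - bin_width, by = bin_width)
  out <- lapply(starts, function(t0) {
    inbin <- age >= t0 & age < t0 + bin_width
    taxa <- rownames(mat)[rowSums(mat[, inbin, drop = FALSE]) > 0]
    assemblage(sprintf("[%g,%g)", t0, t0 + bin_width), taxa)
  })
  attr(out, "excluded") <- excluded
  out
}

#' Turnover between consecutive assemblages
#'
#' Beta-diversity between each pair of consecutive bins; pairs involving an
#' empty placeholder bin yield NA.
#'
#' @param assemblages ordered list of [assemblage()]s (>= 2).
#' @param method passed to [beta_dissimilarity()].
#' @return Data frame: from, to, beta.
#' @export
turnover_series <- function(assemblages, method = "sorensen") {
  if (length(assemblages) < 2L) {
    abort_invalid("need at least 2 assemblages for a turnover series")
  }
  n <- length(assemblages)
  beta <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- assemblages[[i]]
    b <- assemblages[[i + 1L]]
    if (!a$empty && !b$empty) beta[i] <- beta_dissimilarity(a, b, method)
  }
  data.frame(from = vapply(assemblages[-n], `[[`, character(1), "label"),
             to = vapply(assemblages[-1], `[[`, character(1), "label"),
             beta = beta, stringsAsFactors = FALSE)
}

# Kruskal stress-1 for a configuration given disparities.
.stress1 <- function(dist_vec, dhat) {
  sqrt(sum((dist_vec - dhat)^2) / sum(dist_vec^2))
}

#' Non-metric multidimensional scaling
#'
#' Embeds samples in k dimensions so that configuration distances are
#' rank-monotone with the input dissimilarities. Each random start
#' alternates (i) isotonic regression of configuration distances on the
#' dissimilarity ranks (primary approach to ties: tied dissimilarities are
#' ordered by current distance, so ties carry no penalty) and (ii) a Guttman
#' majorization update of the configuration; iteration stops when the
#' Kruskal stress-1 improvement falls below `tol`, the iteration budget is
#' exhausted, or a step fails to improve (the pre-step configuration is
#' kept, so the recorded stress trace is non-increasing). The lowest-stress
#' start is reported, centred and rotated to its principal axes with a
#' deterministic sign convention.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param k embedding dimension (k < n - 1; default 3).
#' @param n_starts random starts (default 50).
#' @param max_iter iteration cap per start (default 500).
#' @param tol stress-change convergence tolerance (default 1e-7).
#' @param seed integer seed; fixed seed and inputs reproduce the solution
#'   bit-identically.
#' @return An object of class `nmds_ordination`: list(points, stress,
#'   stress_trace, n_starts, converged, degenerate, k).
#' @export
nmds_ordinate <- function(d, k = 3, n_starts = 50, max_iter = 500,
                          tol = 1e-7, seed = 1) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || !all(is.finite(d))) {
    abort_invalid("`d` must be a finite square matrix")
  }
  if (!isSymmetric(unname(d), tol = 1e-10)) abort_invalid("`d` must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort_invalid("`d` must have a zero diagonal")
  n <- nrow(d)
  if (!.is_count(k) || k >= n - 1 || k < 1) abort_invalid("`k` must satisfy 1 <= k < n - 1")
  dvec <- d[lower.tri(d)]
  degenerate <- (max(dvec) - min(dvec)) < 1e-12
  if (degenerate) warning("all dissimilarities equal: ordination is degenerate")

  run_start <- function(X) {
    trace <- numeric(0)
    prev <- Inf
    Xprev <- X
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dist_vec <- as.vector(stats::dist(X))
      o <- order(dvec, dist_vec)
      dhat <- numeric(length(dvec))
      dhat[o] <- stats::isoreg(dist_vec[o])$yf
      s <- .stress1(dist_vec, dhat)
      if (s > prev) {       # majorization step failed to improve: keep previous
        X <- Xprev
        break
      }
      trace <- c(trace, s)
      if (prev - s < tol) {
        converged <- TRUE
        Xprev <- X
        break
      }
      prev <- s
      Xprev <- X
      # Guttman transform
      R <- matrix(0, n, n)
      R[lower.tri(R)] <- ifelse(dist_vec > 0, dhat / dist_vec, 0)
      R <- R + t(R)
      B <- -R
      diag(B) <- rowSums(R)
      X <- B %*% X / n
    }
    list(X = Xprev, stress = trace[length(trace)], trace = trace,
         converged = converged)
  }

  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      X0 <- matrix(stats::runif(n * k, -1, 1), n, k)
      res <- run_start(X0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
  })
  X <- scale(best$X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  for (j in seq_len(k)) {         # deterministic axis signs
    i0 <- which.max(abs(X[, j]))
    if (X[i0, j] < 0) X[, j] <- -X[, j]
  }
  rownames(X) <- rownames(d)
  colnames(X) <- sprintf("NMDS%d", seq_len(k))
  structure(list(points = X, stress = best$stress,
                 stress_trace = best$trace, n_starts = n_starts,
                 converged = best$converged, degenerate = degenerate, k = k),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("<nmds_ordination> k=%d, n=%d, stress=%.4f (%d starts%s)\n",
              x$k, nrow(x$points), x$stress, x$n_starts,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Pairwise sample dissimilarity matrix from a taxon table
#'
#' @param m a `count_matrix` or `relative_abundance`.
#' @param method passed to [beta_dissimilarity()].
#' @return Symmetric matrix of dissimilarities between samples.
#' @export
sample_dissimilarity <- function(m, method = "sorensen") {
  mat <- if (inherits(m, "relative_abundance")) m$abundance else m$counts
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- if (method == "bray") {
        beta_dissimilarity(mat[, i], mat[, j], method = "bray")
      } else {
        beta_dissimilarity(rownames(mat)[mat[, i] > 0],
                           rownames(mat)[mat[, j] > 0], method = method)
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Pearson correlations of variables with ordination axes
#'
#' For every (variable, axis) pair: Pearson r, the t statistic
#' t = r sqrt((n-2)/(1-r^2)), and the two-sided p from the t distribution
#' with n - 2 df; `significant` flags p < alpha (raw, no multiplicity
#' adjustment by default, with an optional Benjamini-Hochberg toggle).
#' Zero-variance variables are flagged and never significant.
#'
#' @param ord an [nmds_ordinate()] result, or a points matrix.
#' @param variables data frame or matrix, samples x variables, rows aligned
#'   with (or named by) the ordination's samples.
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return Data frame: variable, axis, r, t, p, significant, flagged.
#' @export
axis_correlations <- function(ord, variables, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pts <- if (inherits(ord, "nmds_ordination")) ord$points else as.matrix(ord)
  v <- as.matrix(variables)
  if (!is.null(rownames(v)) && !is.null(rownames(pts))) {
    v <- v[rownames(pts), , drop = FALSE]
  }
  n <- nrow(pts)
  if (n < 3) abort_invalid("need at least 3 samples")
  if (nrow(v) != n) abort_invalid("variables and ordination must cover the same samples")
  rows <- list()
  for (vn in colnames(v) %||% sprintf("V%d", seq_len(ncol(v)))) {
    x <- v[, vn]
    for (ax in colnames(pts)) {
      if (stats::sd(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = vn, axis = ax, r = NA_real_, t = NA_real_, p = NA_real_,
          significant = FALSE, flagged = TRUE)
        next
      }
      ct <- stats::cor.test(x, pts[, ax], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = vn, axis = ax, r = unname(ct$estimate),
        t = unname(ct$statistic), p = ct$p.value,
        significant = NA, flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  p_use <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(p_use) & p_use < alpha
  out
}

#' Growth-form composition per sample
#'
#' Sums abundance by plant growth form (from a genus-level trait table) and
#' renormalizes over classified genera; genera absent from the trait table
#' are reported separately, not silently dropped into a form.
#'
#' @param m a `relative_abundance` (or matrix with genus names as rownames).
#' @param traits data frame with columns `genus` and `form`.
#' @param vocabulary allowed growth forms.
#' @return list(proportions = forms x samples matrix, unclassified = genera
#'   without a trait entry, unclassified_share = their per-sample summed
#'   abundance).
#' @export
growthform_proportions <- function(m, traits,
                                   vocabulary = c("tree", "shrub", "dwarf-shrub",
                                                  "forb", "graminoid", "aquatic")) {
  if (!all(c("genus", "form") %in% names(traits))) {
    abort_invalid("`traits` needs columns genus and form")
  }
  badform <- setdiff(unique(traits$form), vocabulary)
  if (length(badform)) {
    abort_invalid(sprintf("growth form(s) outside the vocabulary: %s",
                          paste(badform, collapse = ", ")))
  }
  mat <- if (inherits(m, "relative_abundance")) m$abundance else as.matrix(m)
  genera <- if (inherits(m, "relative_abundance")) {
    unname(m$taxon_names[rownames(mat)])
  } else rownames(mat)
  form <- traits$form[match(genera, traits$genus)]
  unclassified <- genera[is.na(form)]
  keep <- !is.na(form)
  props <- matrix(0, length(vocabulary), ncol(mat),
                  dimnames = list(vocabulary, colnames(mat)))
  if (any(keep)) {
    agg <- rowsum(mat[keep, , drop = FALSE], group = form[keep])
    props[rownames(agg), ] <- agg
    tot <- colSums(props)
    props <- sweep(props, 2, ifelse(tot > 0, tot, 1), "/")
  }
  list(proportions = props, unclassified = unclassified,
       unclassified_share = colSums(mat[!keep, , drop = FALSE]))
}
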