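# Design construction: turns a model_spec + data into the matrices and
# parameter map used by the log posterior, the sampler and prediction.

code_factor <- function(x, levels) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad)) stop("unknown factor level: ", x[which(bad)[1]])
  C <- orthonormal_contrasts(length(levels))
  C[match(x, levels), , drop = FALSE]
}

is_factor_like <- function(x) is.character(x) || is.factor(x) || is.logical(x)

# Code one variable into its design columns, recording factor metadata.
code_var <- function(var, data, spec, meta) {
  x <- data[[var]]
  if (is.null(x)) stop("predictor not found in data: ", var)
  if (var %in% spec$factors || is_factor_like(x)) {
    levels <- meta$factor_levels[[var]]
    if (is.null(levels)) levels <- sort(unique(as.character(x)))
    M <- code_factor(x, levels)
    colnames(M) <- if (ncol(M) == 1) var else
      paste0(var, seq_len(ncol(M)))
    attr(M, "levels") <- levels
    M
  } else {
    M <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, var))
    M
  }
}

# Columns for a fixed term label, possibly an interaction "a:b".
code_term <- function(label, data, spec, meta) {
  vars <- strsplit(label, ":", fixed = TRUE)[[1]]
  mats <- lapply(vars, code_var, data = data, spec = spec, meta = meta)
  M <- mats[[1]]
  if (length(mats) > 1) {
    for (k in 2:length(mats)) {
      A <- M; B <- mats[[k]]
      cols <- list()
      nms <- character()
      for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
        cols[[length(cols) + 1]] <- A[, i] * B[, j]
        nms <- c(nms, paste0(colnames(A)[i], ":", colnames(B)[j]))
      }
      M <- do.call(cbind, cols)
      colnames(M) <- nms
    }
  }
  list(M = M, mats = mats, vars = vars)
}

empirical_link_mean <- function(spec, data, trials) {
  y <- data[[spec$response]]
  switch(spec$family,
         binomial = {
           p <- sum(y) / sum(trials)
           p <- min(max(p, 1e-3), 1 - 1e-3)
           stats::qlogis(p)
         },
         gaussian = mean(y),
         gamma = log(mean(y)))
}

#' Build the numerical design for a model
#'
#' Internal workhorse: expands the fixed terms (orthonormal factor coding),
#' the smooth terms (mixed-model thin-plate reparameterization: null-space
#' columns join the fixed matrix, penalized columns become iid random-effect
#' blocks with their own SD), the monotonic terms and the grouped random
#' effects, and records everything needed to rebuild the design for new data.
#'
#' @param spec a \code{model_spec}.
#' @param data model table (data.frame).
#' @return a \code{model_design} list.
#' @keywords internal
build_design <- function(spec, data) {
  n <- nrow(data)
  y <- as.numeric(data[[spec$response]])
  if (is.null(y) || anyNA(y)) stop("response missing or has NAs")
  trials <- NULL
  if (spec$family == "binomial") {
    trials <- if (is.character(spec$trials)) as.numeric(data[[spec$trials]])
              else rep(as.numeric(spec$trials), n)
    if (any(y < 0 | y > trials)) stop("binomial response outside [0, trials]")
  }
  if (spec$family == "gamma" && any(y <= 0))
    stop("gamma response must be positive")
  se <- if (!is.null(spec$se)) as.numeric(data[[spec$se]]) else NULL

  meta <- list(factor_levels = list())
  # pre-register factor levels so prediction uses identical coding
  all_vars <- unique(unlist(c(
    lapply(spec$fixed, function(l) strsplit(l, ":", fixed = TRUE)[[1]]),
    lapply(spec$smooths, function(s) s$by),
    if (!is.null(spec$random)) setdiff(spec$random$terms, "1"))))
  for (v in all_vars) {
    x <- data[[v]]
    if (is.null(x)) stop("predictor not found in data: ", v)
    if (v %in% spec$factors || is_factor_like(x))
      meta$factor_levels[[v]] <- sort(unique(as.character(x)))
  }

  X_cols <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  for (label in spec$fixed)
    X_cols[[label]] <- code_term(label, data, spec, meta)$M

  blocks <- list()
  smooth_meta <- list()
  for (si in seq_along(spec$smooths)) {
    st <- spec$smooths[[si]]
    xv <- as.numeric(data[[st$var]])
    if (is.null(data[[st$var]])) stop("smooth covariate not found: ", st$var)
    base_label <- sprintf("s(%s)", st$var)
    mixed <- tprs_mixed(xv, st$k)
    colnames(mixed$Xf) <- paste0(base_label, ".lin")
    X_cols[[base_label]] <- mixed$Xf
    blocks[[length(blocks) + 1]] <- list(
      type = "smooth", label = base_label, Z = mixed$Zr, q = ncol(mixed$Zr))
    sm_entry <- list(term = st, mixed = mixed, cells = NULL)
    if (!is.null(st$by)) {
      cell_f <- interaction(lapply(st$by, function(v)
        as.character(data[[v]])), sep = ".", drop = FALSE)
      cells <- sort(unique(as.character(cell_f)))
      sm_entry$cells <- list(by = st$by, levels = cells, mixed = list())
      for (cl in cells) {
        mask <- as.character(cell_f) == cl
        mc <- tprs_mixed(xv[mask], st$k)
        lab <- sprintf("s(%s):%s", st$var, cl)
        Xf <- matrix(0, n, ncol(mc$Xf), dimnames = list(NULL, paste0(lab, ".lin")))
        Xf[mask, ] <- mc$Xf
        Zr <- matrix(0, n, ncol(mc$Zr))
        Zr[mask, ] <- mc$Zr
        X_cols[[lab]] <- Xf
        blocks[[length(blocks) + 1]] <- list(type = "smooth", label = lab,
                                             Z = Zr, q = ncol(Zr))
        sm_entry$cells$mixed[[cl]] <- mc
      }
    }
    smooth_meta[[si]] <- sm_entry
  }

  mono_meta <- list()
  for (mv in spec$monotonic) {
    xm <- as.integer(data[[mv]])
    if (is.null(data[[mv]])) stop("monotonic predictor not found: ", mv)
    if (any(xm < 0)) stop("monotonic predictor must be a nonnegative ordinal")
    D <- max(xm)
    if (D < 1) stop("monotonic predictor is constant: ", mv)
    blocks[[length(blocks) + 1]] <- list(type = "mono", label = paste0("mo(", mv, ")"),
                                         var = mv, x = xm, D = D)
    mono_meta[[mv]] <- list(D = D)
  }

  if (!is.null(spec$random)) {
    rt <- spec$random
    gx <- as.character(data[[rt$group]])
    if (is.null(data[[rt$group]])) stop("grouping variable not found: ", rt$group)
    groups <- sort(unique(gx))
    gidx <- match(gx, groups)
    Tm <- matrix(1, n, 1, dimnames = list(NULL, "1"))
    for (tv in setdiff(rt$terms, "1")) {
      M <- code_var(tv, data, spec, meta)
      if (ncol(M) != 1)
        stop("random slope terms must code to a single column: ", tv)
      Tm <- cbind(Tm, M)
    }
    blocks[[length(blocks) + 1]] <- list(
      type = "group", label = paste0("(", paste(rt$terms, collapse = "+"),
                                     "|", rt$group, ")"),
      group = rt$group, groups = groups, gidx = gidx, Tm = Tm,
      J = length(groups), K = ncol(Tm),
      correlated = rt$correlated && ncol(Tm) > 1)
  }

  X <- do.call(cbind, X_cols)
  # center non-intercept columns: decorrelates the intercept from predictor
  # means; the intercept prior location then applies at the covariate means
  x_centers <- c(0, colMeans(X[, -1, drop = FALSE]))
  X <- sweep(X, 2, x_centers)
  p <- ncol(X)
  pr <- spec$priors
  beta_loc <- rep(0, p)
  beta_scale <- rep(pr$fixed_scale, p)
  beta_loc[1] <- if (!is.null(pr$intercept_location)) pr$intercept_location
                 else empirical_link_mean(spec, data, trials)
  beta_scale[1] <- pr$intercept_scale

  design <- list(spec = spec, n = n, y = y, trials = trials, se = se,
                 X = X, p = p, x_centers = x_centers,
                 beta_loc = beta_loc, beta_scale = beta_scale,
                 blocks = blocks, meta = meta, smooth_meta = smooth_meta,
                 mono_meta = mono_meta, data = data)
  design$pmap <- make_param_map(design)
  class(design) <- "model_design"
  design
}

# Parameter packing: one flat unconstrained vector.
make_param_map <- function(design) {
  nm <- colnames(design$X)
  entries <- list(list(what = "beta", n = design$p, names = paste0("b_", nm)))
  for (bi in seq_along(design$blocks)) {
    b <- design$blocks[[bi]]
    if (b$type == "smooth") {
      entries <- c(entries, list(
        list(what = "smooth_u", block = bi, n = b$q,
             names = sprintf("%s.u%d", b$label, seq_len(b$q))),
        list(what = "smooth_logsd", block = bi, n = 1,
             names = paste0("log_sd_", b$label))))
    } else if (b$type == "mono") {
      entries <- c(entries, list(
        list(what = "mono_beta", block = bi, n = 1, names = paste0("b_", b$label)),
        list(what = "mono_u", block = bi, n = b$D - 1,
             names = sprintf("%s.zeta_raw%d", b$label, seq_len(b$D - 1)))))
    } else if (b$type == "group") {
      ncor <- if (b$correlated) b$K * (b$K - 1) / 2 else 0
      entries <- c(entries, list(
        list(what = "group_z", block = bi, n = b$J * b$K,
             names = sprintf("z_%s[%d,%d]", b$group,
                             rep(seq_len(b$J), b$K), rep(seq_len(b$K), each = b$J))),
        list(what = "group_logtau", block = bi, n = b$K,
             names = paste0("log_sd_", b$group, "_", colnames(b$Tm)))))
      if (ncor > 0)
        entries <- c(entries, list(
          list(what = "group_corr", block = bi, n = ncor,
               names = sprintf("corr_raw_%s%d", b$group, seq_len(ncor)))))
    }
  }
  if (design$spec$family == "gaussian")
    entries <- c(entries, list(list(what = "log_sigma", n = 1, names = "log_sigma")))
  if (design$spec$family == "gamma")
    entries <- c(entries, list(list(what = "log_shape", n = 1, names = "log_shape")))
  off <- 0
  for (i in seq_along(entries)) {
    entries[[i]]$idx <- off + seq_len(entries[[i]]$n)
    off <- off + entries[[i]]$n
  }
  list(entries = entries, n_par = off,
       names = unlist(lapply(entries, `[[`, "names")))
}

pmap_idx <- function(pmap, what, block = NULL) {
  for (e in pmap$entries)
    if (e$what == what && (is.null(block) || identical(e$block, block)))
      return(e$idx)
  integer(0)
}

# reference softmax: zeta = softmax(c(0, u)); returns simplex of length D
simplex_from_raw <- function(u) {
  e <- exp(c(0, u) - max(c(0, u)))
  e / sum(e)
}

# Cholesky factor of a correlation matrix from unconstrained canonical
# partial correlations (row-major lower triangle), plus the log-Jacobian of
# the transform and the LKJ log-density.
chol_from_raw <- function(y, K, lkj_eta = 2) {
  L <- diag(K)
  logjac <- 0
  pos <- 0
  for (i in 2:K) {
    for (j in 1:(i - 1)) {
      pos <- pos + 1
      z <- tanh(y[pos])
      w <- sqrt(max(1 - sum(L[i, seq_len(j - 1)]^2), 1e-12))
      L[i, j] <- z * w
      logjac <- logjac + log(w) + log(max(1 - z^2, 1e-300))
    }
    L[i, i] <- sqrt(max(1 - sum(L[i, seq_len(i - 1)]^2), 1e-12))
  }
  lkj <- sum((K - (2:K) + 2 * lkj_eta - 2) * log(diag(L)[2:K]))
  list(L = L, logjac = logjac, lkj = lkj)
}
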