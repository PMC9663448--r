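# GAM-based multiple regression on distance matrices (MRM) with permutation
# inference, deviance partitioning under fixed smoothing, and jackknife
# sensitivity by study.

#' Specify a GAM-MRM model
#'
#' @param response Name of the response distance matrix.
#' @param parametric_terms Names of binary (boundary) matrices entered as
#'   0/1 parametric indicators. The indicator is coded 1 = "same region"
#'   (i.e. `1 - distance`), so a negative estimate means lower dissimilarity
#'   within regions.
#' @param smooth_terms Names of quantitative matrices entered as thin-plate
#'   regression spline smooths.
#' @param basis_dim Spline basis dimension per smooth (default 10).
#' @param n_perm Number of response-matrix permutations (default 1000; 0
#'   skips permutation inference).
#' @param seed Integer seed for the permutations.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, parametric_terms = character(),
                       smooth_terms = character(), basis_dim = 10L,
                       n_perm = 1000L, seed = 1L) {
  stopifnot(length(response) == 1L, n_perm >= 0, basis_dim >= 3)
  if (anyDuplicated(c(parametric_terms, smooth_terms))) {
    stop("duplicated term names", call. = FALSE)
  }
  structure(list(response = response,
                 parametric_terms = parametric_terms,
                 smooth_terms = smooth_terms,
                 basis_dim = as.integer(basis_dim),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# align matrices on a common sorted label set and vectorize all of them;
# binary parametric matrices become same-region indicators (1 - distance)
build_design <- function(data, spec) {
  need <- unique(c(spec$response, spec$parametric_terms, spec$smooth_terms))
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("distance matrix not supplied: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- sort(dm_labels(data[[spec$response]]))
  for (nm in need) {
    if (!setequal(dm_labels(data[[nm]]), labels)) {
      stop("matrix '", nm, "' is not aligned with the response labels",
           call. = FALSE)
    }
  }
  vecs <- lapply(data[need], vectorize_lower_triangle, label_order = labels)
  df <- as.data.frame(lapply(vecs, `[[`, "values"))
  names(df) <- need
  for (nm in spec$parametric_terms) {
    if (dm_kind(data[[nm]]) == "binary") df[[nm]] <- 1 - df[[nm]]
  }
  list(design = df, pairs = vecs[[spec$response]]$pairs, labels = labels)
}

# formula + per-smooth basis dimension (capped below unique-value count)
mrm_formula <- function(spec, design) {
  terms <- spec$parametric_terms
  for (nm in spec$smooth_terms) {
    nu <- length(unique(design[[nm]]))
    k <- min(spec$basis_dim, nu - 1L)
    if (nu < 5L) {
      warning("smooth term '", nm, "' has too few unique values; ",
              "entering linearly", call. = FALSE)
      terms <- c(terms, nm)
    } else {
      terms <- c(terms, sprintf("s(%s, k = %d, bs = \"tp\")", nm, k))
    }
  }
  if (length(terms) == 0L) terms <- "1"
  stats::as.formula(paste(".response ~", paste(terms, collapse = " + ")))
}

#' Fit the additive model stage of a GAM-MRM
#'
#' Penalized Gaussian additive fit with thin-plate regression spline bases
#' and REML smoothing selection (via mgcv). Exposed separately so reduced
#' and permuted fits share one code path.
#'
#' @param design Data frame of pair-level predictors (one row per unordered
#'   network pair).
#' @param response Numeric vector of pair-level dissimilarities.
#' @param spec A [model_spec()].
#' @param sp Optional fixed smoothing parameters (as from a previous fit);
#'   when supplied, REML estimation is skipped.
#' @return The fitted `gam` object.
#' @export
fit_additive_model <- function(design, response, spec, sp = NULL) {
  if (anyNA(design) || anyNA(response)) {
    stop("missing values in the design or response", call. = FALSE)
  }
  df <- design
  df$.response <- response
  fml <- withCallingHandlers(
    mrm_formula(spec, design),
    warning = function(w) invokeRestart("muffleWarning"))
  fit <- mgcv::gam(fml, data = df, method = "REML", sp = sp)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient fit; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit
}

# extract the statistics the permutation test needs
fit_stats <- function(fit) {
  sm <- summary(fit)
  list(p_table = sm$p.table, s_table = sm$s.table,
       dev_expl = sm$dev.expl, sp = fit$sp)
}

#' GAM-based multiple regression on distance matrices
#'
#' Fits a Gaussian GAM on the vectorized lower triangles of aligned distance
#' matrices and tests each term by permutation: each iteration draws a
#' permutation of the network labels, applies it simultaneously to the rows
#' and columns of the response matrix only, re-vectorizes and refits,
#' recording `|t|` for parametric terms and `F` for smooths. Permutation
#' p-values include the observed statistic:
#' `p = (1 + #extreme) / (n_perm + 1)`.
#'
#' @param data Named list of `dist_matrix` objects sharing one label set.
#' @param spec A [model_spec()].
#' @param fast_perm If `TRUE`, permutation refits freeze the smoothing
#'   parameters at their observed-fit values instead of re-estimating them
#'   by REML. This is faster but anticonservative for smooth terms whose
#'   smoothing the observed response influenced; keep the default `FALSE`
#'   for inference.
#' @param progress Print a dot every 100 permutations.
#' @return A `gammrm_result`: parametric and smooth-term tables with
#'   permutation p-values, deviance explained, the fitted `gam` object, and
#'   bookkeeping fields.
#' @export
gam_mrm <- function(data, spec, fast_perm = FALSE, progress = FALSE) {
  bd <- build_design(data, spec)
  n <- length(bd$labels)
  if (n < 4L) stop("need at least 4 networks for permutation inference",
                   call. = FALSE)
  resp_mat <- unclass(data[[spec$response]])[bd$labels, bd$labels]
  tri <- which(upper.tri(resp_mat), arr.ind = TRUE)
  tri <- tri[order(tri[, 1], tri[, 2]), , drop = FALSE]

  design <- bd$design[, setdiff(names(bd$design), spec$response),
                      drop = FALSE]
  y_obs <- bd$design[[spec$response]]
  fit <- fit_additive_model(design, y_obs, spec)
  obs <- fit_stats(fit)

  par_names <- rownames(obs$p_table)
  sm_names <- rownames(obs$s_table)
  t_obs <- obs$p_table[, "t value"]
  f_obs <- if (length(sm_names)) obs$s_table[, "F"] else numeric(0)

  n_perm <- spec$n_perm
  if (n_perm > 0L) {
    count_t <- stats::setNames(numeric(length(par_names)), par_names)
    count_f <- stats::setNames(numeric(length(sm_names)), sm_names)
    # the design never changes under response permutation, so refits reuse
    # the preprocessed model structure and only swap the response; with
    # fast_perm the smoothing parameters are additionally frozen at their
    # observed-fit values (anticonservative for smooth terms - see the
    # methods vignette), otherwise they are re-estimated by REML per
    # permutation
    sp_fix <- if (fast_perm) obs$sp else NULL
    df0 <- design
    df0$.response <- y_obs
    fml <- withCallingHandlers(
      mrm_formula(spec, design),
      warning = function(w) invokeRestart("muffleWarning"))
    g_pre <- mgcv::gam(fml, data = df0, sp = sp_fix, method = "REML",
                       fit = FALSE)
    refit <- function(yp) {
      g_pre$y <- yp
      g_pre$mf$.response <- yp
      mgcv::gam(G = g_pre)
    }
    with_seed(spec$seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        yp <- resp_mat[perm, perm][tri]
        pfit <- refit(yp)
        ps <- fit_stats(pfit)
        count_t <- count_t +
          (abs(ps$p_table[, "t value"]) >= abs(t_obs) - 1e-12)
        if (length(sm_names)) {
          count_f <- count_f + (ps$s_table[, "F"] >= f_obs - 1e-12)
        }
        if (progress && b %% 100 == 0) cat(".")
      }
    })
    p_t <- (1 + count_t) / (n_perm + 1)
    p_f <- (1 + count_f) / (n_perm + 1)
  } else {
    p_t <- stats::setNames(rep(NA_real_, length(par_names)), par_names)
    p_f <- stats::setNames(rep(NA_real_, length(sm_names)), sm_names)
  }
  if (progress && n_perm >= 100) cat("\n")

  parametric <- data.frame(
    term = par_names,
    estimate = obs$p_table[, "Estimate"],
    t = t_obs,
    p_perm = unname(p_t),
    row.names = NULL, stringsAsFactors = FALSE)
  smooths <- data.frame(
    term = sm_names,
    edf = if (length(sm_names)) obs$s_table[, "edf"] else numeric(0),
    F = f_obs,
    p_perm = unname(p_f),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(parametric = parametric, smooths = smooths,
                 deviance_explained = obs$dev_expl,
                 n_pairs = nrow(design), n_networks = n,
                 n_perm = n_perm, seed = spec$seed, spec = spec,
                 fit = fit, pairs = bd$pairs),
            class = "gammrm_result")
}

#' @export
print.gammrm_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "GAM-MRM: %d networks, %d pairs, %d permutations (seed %d)\n",
    x$n_networks, x$n_pairs, x$n_perm, x$seed))
  cat("\nParametric coefficients:\n")
  print(format(x$parametric, digits = digits), row.names = FALSE)
  if (nrow(x$smooths)) {
    cat("\nSmooth terms:\n")
    print(format(x$smooths, digits = digits), row.names = FALSE)
  }
  cat(sprintf("\nDeviance explained: %.1f%%\n",
              100 * x$deviance_explained))
  invisible(x)
}

#' Write a result as a flat table (term, estimate/EDF, t/F, p)
#'
#' @param x A `gammrm_result`.
#' @param path Output TSV path (optional).
#' @return The combined table, invisibly when writing.
#' @export
result_table <- function(x, path = NULL) {
  par <- data.frame(term = x$parametric$term, type = "parametric",
                    estimate_or_edf = x$parametric$estimate,
                    statistic = x$parametric$t,
                    p_perm = x$parametric$p_perm,
                    stringsAsFactors = FALSE)
  sm <- if (nrow(x$smooths)) {
    data.frame(term = x$smooths$term, type = "smooth",
               estimate_or_edf = x$smooths$edf, statistic = x$smooths$F,
               p_perm = x$smooths$p_perm, stringsAsFactors = FALSE)
  }
  out <- rbind(par, sm)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Deviance partitioning over variables of interest
#'
#' Fits the full model by REML, then refits every reduced model (all
#' subsets of the variables of interest removed, control terms always kept)
#' with the smoothing parameters of the retained smooths frozen at their
#' full-model values, and decomposes the explained deviance attributable to
#' the variables of interest into unique and shared (Venn) components by
#' inclusion-exclusion. Negative components are retained and flagged.
#'
#' @param data Named list of `dist_matrix` objects.
#' @param spec A [model_spec()]; terms not in `variables_of_interest` act as
#'   controls present in every model.
#' @param variables_of_interest Character subset of the model's terms.
#' @param max_vars Guard on the exponential subset count (default 5).
#' @return A `deviance_partition`: `components` data frame (one row per
#'   nonempty subset, `:`-joined names), `residual`, `full_deviance`,
#'   `controls_deviance`.
#' @export
deviance_partition <- function(data, spec, variables_of_interest,
                               max_vars = 5L) {
  voi <- variables_of_interest
  all_terms <- c(spec$parametric_terms, spec$smooth_terms)
  if (!all(voi %in% all_terms)) {
    stop("variables_of_interest must be model terms", call. = FALSE)
  }
  if (length(voi) > max_vars) {
    stop("more than ", max_vars, " variables of interest (2^k reduced ",
         "models); raise max_vars deliberately if needed", call. = FALSE)
  }
  bd <- build_design(data, spec)
  design <- bd$design[, setdiff(names(bd$design), spec$response),
                      drop = FALSE]
  y <- bd$design[[spec$response]]
  full_fit <- fit_additive_model(design, y, spec)
  sp_full <- smooth_sp_by_term(full_fit)

  controls <- setdiff(all_terms, voi)
  k <- length(voi)
  subset_dev <- numeric(2^k)          # dev.expl of controls + subset
  for (mask in 0:(2^k - 1)) {
    inc <- voi[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    terms_now <- c(controls, inc)
    sub_spec <- spec
    sub_spec$parametric_terms <- intersect(spec$parametric_terms, terms_now)
    sub_spec$smooth_terms <- intersect(spec$smooth_terms, terms_now)
    if (mask == 2^k - 1) {
      subset_dev[mask + 1] <- summary(full_fit)$dev.expl
    } else {
      sp <- sp_for_terms(sp_full, sub_spec, design)
      sub_fit <- fit_additive_model(design, y, sub_spec, sp = sp)
      subset_dev[mask + 1] <- summary(sub_fit)$dev.expl
    }
  }
  r_empty <- subset_dev[1]
  r_full <- subset_dev[2^k]
  total <- r_full - r_empty
  # g(B) = total - R(V \ B) + R(empty); Moebius inversion gives components
  g <- vapply(0:(2^k - 1), function(mask) {
    comp <- bitwAnd(bitwNot(mask), 2^k - 1)
    total - subset_dev[comp + 1] + r_empty
  }, numeric(1))
  comps <- data.frame(subset = character(0), deviance = numeric(0),
                      stringsAsFactors = FALSE)
  for (mask in 1:(2^k - 1)) {
    val <- 0
    sub <- mask
    repeat {                          # sum over sub-masks b of mask
      sign <- (-1)^(bitcount(mask) - bitcount(sub))
      val <- val + sign * g[sub + 1]
      if (sub == 0) break
      sub <- bitwAnd(sub - 1, mask)
    }
    nm <- paste(voi[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0], collapse = ":")
    comps <- rbind(comps, data.frame(subset = nm, deviance = val,
                                     stringsAsFactors = FALSE))
  }
  comps$negative <- comps$deviance < 0
  structure(list(components = comps,
                 variables_of_interest = voi,
                 residual = 1 - r_full,
                 full_deviance = r_full,
                 controls_deviance = r_empty),
            class = "deviance_partition")
}

bitcount <- function(x) {
  n <- 0L
  while (x > 0) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

#' @export
print.deviance_partition <- function(x, digits = 4, ...) {
  cat("Deviance partition over:",
      paste(x$variables_of_interest, collapse = ", "), "\n")
  print(format(x$components, digits = digits), row.names = FALSE)
  cat(sprintf("controls: %.4f  full model: %.4f  residual: %.4f\n",
              x$controls_deviance, x$full_deviance, x$residual))
  invisible(x)
}

# named smoothing parameters of a fit, keyed by the smooth's covariate
smooth_sp_by_term <- function(fit) {
  if (length(fit$smooth) == 0L) return(stats::setNames(numeric(0),
                                                       character(0)))
  nms <- vapply(fit$smooth, function(s) s$term, character(1))
  sp <- numeric(0)
  labs <- character(0)
  for (i in seq_along(fit$smooth)) {
    s <- fit$smooth[[i]]
    idx <- seq(s$first.sp, s$last.sp)
    sp <- c(sp, fit$sp[idx])
    labs <- c(labs, rep(nms[i], length(idx)))
  }
  stats::setNames(sp, labs)
}

# smoothing-parameter vector for a reduced spec, in formula order
sp_for_terms <- function(sp_full, spec, design) {
  keep <- character(0)
  for (nm in spec$smooth_terms) {
    if (length(unique(design[[nm]])) >= 5L) keep <- c(keep, nm)
  }
  if (length(keep) == 0L) return(NULL)
  unname(sp_full[keep])
}

#' Jackknife the model by study
#'
#' Drops one study at a time, rebuilds every distance matrix on the reduced
#' network set via the user-supplied recipe, refits the model without
#' permutations, and tabulates each term's t (parametric) or F (smooth)
#' statistic.
#'
#' @param nets List of `interaction_matrix` objects.
#' @param metadata Site metadata covering the networks (with `study_id`).
#' @param build_data Function `(nets, metadata) -> named list of
#'   dist_matrix` producing the response and predictors named in `spec`.
#' @param spec A [model_spec()]; its `n_perm` is ignored here.
#' @return Data frame: one row per study with `study_id`,
#'   `n_networks_dropped`, `skipped`, and `t_*` / `F_*` columns.
#' @export
jackknife_by_study <- function(nets, metadata, build_data, spec) {
  ids <- vapply(nets, network_id, character(1))
  md <- metadata[match(ids, metadata$network_id), ]
  studies <- unique(md$study_id)
  rows <- vector("list", length(studies))
  spec0 <- spec
  spec0$n_perm <- 0L
  for (si in seq_along(studies)) {
    s <- studies[si]
    keep <- md$study_id != s
    base <- data.frame(study_id = s, n_networks_dropped = sum(!keep),
                       skipped = FALSE, stringsAsFactors = FALSE)
    if (sum(keep) < 4L) {
      base$skipped <- TRUE
      rows[[si]] <- base
      next
    }
    data_s <- build_data(nets[keep], md[keep, ])
    res <- gam_mrm(data_s, spec0)
    for (r in seq_len(nrow(res$parametric))) {
      base[[paste0("t_", res$parametric$term[r])]] <-
        res$parametric$t[r]
    }
    for (r in seq_len(nrow(res$smooths))) {
      base[[paste0("F_", res$smooths$term[r])]] <- res$smooths$F[r]
    }
    rows[[si]] <- base
  }
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(nm, names(r))) r[[col]] <- NA_real_
    r[nm]
  })
  do.call(rbind, rows)
}
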