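#' Classify CP components as image-, omission-specific or nonspecific
#'
#' For each component the trial weights on image trials are compared with
#' those on omission trials by the two-sided Wilcoxon rank-sum test.
#' Components with `p >= alpha` are nonspecific; significant components are
#' assigned to the condition with the larger mean absolute trial weight.
#'
#' By default the rank-sum is computed on the *absolute* trial weights, so
#' that a component whose omission weights are large in magnitude but
#' symmetric about zero (the signature of a shared state-driven signal
#' expressed on omission trials) is still condition-specific; `signed`
#' compares the raw weights instead. Because the CP sign gauge is arbitrary,
#' only magnitudes are sign-invariant, which is why `absolute` is the
#' default.
#'
#' @param model A `tca_model`.
#' @param trial_labels data.frame with a `condition` column
#'   (`"image"`/`"omission"`) covering the model's trials.
#' @param alpha Significance level (default 0.05).
#' @param classify_on `"absolute"` (default) or `"signed"`: whether the
#'   rank-sum test compares absolute or raw trial weights.
#' @return A `component_labels` data.frame: `component`, `specificity`,
#'   `p_value`, `mean_abs_image`, `mean_abs_omission`, `sd_image`,
#'   `sd_omission`.
#' @export
classify_components <- function(model, trial_labels, alpha = 0.05,
                                classify_on = c("absolute", "signed")) {
  classify_on <- match.arg(classify_on)
  stopifnot(inherits(model, "tca_model"))
  cond <- trial_labels$condition
  if (length(cond) != nrow(model$trial_factor)) {
    stop("trial labels do not cover the model's trials", call. = FALSE)
  }
  img <- cond == "image"
  omi <- cond == "omission"
  if (!any(img) || !any(omi)) {
    stop("both conditions must be non-empty", call. = FALSE)
  }
  W <- component_weights(model, "trial", scaled = TRUE)
  rows <- lapply(seq_len(model$rank), function(r) {
    wi <- W[img, r]; wo <- W[omi, r]
    p <- if (classify_on == "absolute") {
      rank_sum_test(abs(wi), abs(wo))$p.value
    } else {
      rank_sum_test(wi, wo)$p.value
    }
    spec <- if (p >= alpha) {
      "nonspecific"
    } else if (mean(abs(wi)) >= mean(abs(wo))) "image" else "omission"
    data.frame(
      component = r, specificity = spec, p_value = p,
      mean_abs_image = mean(abs(wi)), mean_abs_omission = mean(abs(wo)),
      sd_image = stats::sd(wi), sd_omission = stats::sd(wo)
    )
  })
  structure(do.call(rbind, rows),
            class = c("component_labels", "data.frame"))
}

#' Count components per specificity category across an ensemble
#'
#' @param label_list List (over ensemble iterations, possibly pooled across
#'   sessions) of `component_labels` data.frames; nested lists are pooled
#'   per iteration.
#' @return List with `per_iteration` (data.frame: iteration, image,
#'   omission, nonspecific) and `summary` (mean and SD per category across
#'   iterations).
#' @export
count_components_by_specificity <- function(label_list) {
  per_it <- lapply(seq_along(label_list), function(i) {
    lab <- label_list[[i]]
    if (is.data.frame(lab)) lab <- list(lab)
    spec <- unlist(lapply(lab, function(x) x$specificity))
    data.frame(
      iteration = i,
      image = sum(spec == "image"),
      omission = sum(spec == "omission"),
      nonspecific = sum(spec == "nonspecific")
    )
  })
  per_iteration <- do.call(rbind, per_it)
  cats <- c("image", "omission", "nonspecific")
  summary <- data.frame(
    specificity = cats,
    mean = vapply(cats, function(c_) mean(per_iteration[[c_]]), numeric(1)),
    sd = vapply(cats, function(c_) stats::sd(per_iteration[[c_]]),
                numeric(1)),
    row.names = NULL
  )
  list(per_iteration = per_iteration, summary = summary)
}

#' Standard deviation of trial weights per component and condition
#'
#' @param model A `tca_model`.
#' @param trial_labels data.frame with `condition`.
#' @param components Component indices (non-empty subset); default all.
#' @return data.frame: `component`, `sd_image`, `sd_omission`, `sd_all`.
#' @export
trial_weight_sd <- function(model, trial_labels,
                            components = seq_len(model$rank)) {
  if (length(components) < 1L) stop("component subset must be non-empty",
                                    call. = FALSE)
  W <- component_weights(model, "trial", scaled = TRUE)
  cond <- trial_labels$condition
  do.call(rbind, lapply(components, function(r) {
    data.frame(
      component = r,
      sd_image = stats::sd(W[cond == "image", r]),
      sd_omission = stats::sd(W[cond == "omission", r]),
      sd_all = stats::sd(W[, r])
    )
  }))
}

#' Shuffle trials within condition, independently per neuron
#'
#' For every neuron, the trial slices are permuted uniformly among image
#' trials and, separately, among omission trials. Labels are untouched, so
#' condition-locked (image/omission-specific) structure is preserved exactly
#' while any *shared* across-neuron trial-to-trial covariation -- the
#' task-independent signal -- is destroyed. Per neuron and condition, the
#' multiset of trial slices (and hence the condition-mean trace) is
#' preserved bit-exactly. A condition with a single trial is left unchanged.
#'
#' @param tensor An `aligned_tensor`.
#' @param trial_labels data.frame with `condition`; defaults to the tensor's
#'   own labels.
#' @param seed Integer seed; deterministic.
#' @return The shuffled `aligned_tensor`.
#' @export
shuffle_within_condition <- function(tensor,
                                     trial_labels = tensor$trial_labels,
                                     seed = 1L) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  cond <- trial_labels$condition
  d <- dim(tensor$data)
  if (length(cond) != d[3L]) {
    stop("labels do not partition the tensor's trials", call. = FALSE)
  }
  out <- tensor
  groups <- split(seq_len(d[3L]), cond)
  with_seed(seed, {
    for (i in seq_len(d[1L])) {
      for (idx in groups) {
        if (length(idx) < 2L) next
        out$data[i, , idx] <- tensor$data[i, , idx[sample.int(length(idx))]]
      }
    }
  })
  out
}

# Superficial / deep split at 250 um imaging depth (250 itself -> deep).
depth_layer <- function(depth) {
  ifelse(depth < 250, "superficial", "deep")
}

# Pool scale-weighted absolute neuronal weights of components with the given
# specificity across an ensemble. Returns data.frame(weight, area, layer,
# iteration) or NULL when no component matches.
pool_neuron_weights <- function(ensemble, trial_labels, neurons,
                                specificity, alpha) {
  rows <- lapply(seq_along(ensemble), function(i) {
    model <- ensemble[[i]]
    lab <- classify_components(model, trial_labels, alpha)
    comps <- lab$component[lab$specificity == specificity]
    if (length(comps) == 0L) return(NULL)
    A <- component_weights(model, "neuron", scaled = TRUE)
    do.call(rbind, lapply(comps, function(r) {
      data.frame(
        weight = abs(A[, r]),
        area = neurons$area,
        layer = depth_layer(neurons$depth),
        iteration = i
      )
    }))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Compare condition-specific neuronal weights between real and shuffled fits
#'
#' Pools the scale-weighted absolute neuronal weights of the
#' condition-specific components (omission-specific by default) across each
#' ensemble, groups them by area and layer (superficial: depth < 250 um;
#' deep: >= 250 um), and tests real against shuffled per group with the
#' rank-sum test on the pooled weights. Because ensemble iterations re-fit
#' the *same* tensor, pooled weights are dependent and the pooled test
#' overstates its effective sample size; the function therefore also reports
#' a calibrated iteration-level test (rank-sum across ensemble members of
#' the per-member mean pooled weight), which is the default inference and
#' the `overall$p_value` entry.
#'
#' @param real_ensemble,shuffled_ensemble Lists of `tca_model`s from
#'   [run_tca_ensemble()] on the real and within-condition-shuffled tensor.
#' @param trial_labels Shared trial labels (`condition` column).
#' @param neurons Neuron metadata with `area` and `depth`.
#' @param specificity `"omission"` (default) or `"image"`.
#' @param alpha Classification significance level.
#' @return List with `groups` (data.frame per area x layer: mean weights,
#'   pooled-test p, direction), `overall` (list: `p_value` = iteration-level
#'   p, `p_pooled`, means, `direction`: +1 when real > shuffled), and the
#'   pooled weight tables.
#' @export
compare_real_vs_shuffled_weights <- function(real_ensemble,
                                             shuffled_ensemble,
                                             trial_labels, neurons,
                                             specificity = c("omission",
                                                             "image"),
                                             alpha = 0.05) {
  specificity <- match.arg(specificity)
  real <- pool_neuron_weights(real_ensemble, trial_labels, neurons,
                              specificity, alpha)
  shuf <- pool_neuron_weights(shuffled_ensemble, trial_labels, neurons,
                              specificity, alpha)
  if (is.null(real) || is.null(shuf)) {
    return(list(groups = NULL, overall = list(
      p_value = NA_real_, p_pooled = NA_real_,
      mean_real = if (is.null(real)) NA_real_ else mean(real$weight),
      mean_shuffled = if (is.null(shuf)) NA_real_ else mean(shuf$weight),
      direction = NA_real_,
      note = "no condition-specific components in one of the ensembles"
    ), real = real, shuffled = shuf))
  }
  group_keys <- sort(unique(c(paste(real$area, real$layer),
                              paste(shuf$area, shuf$layer))))
  groups <- do.call(rbind, lapply(group_keys, function(k) {
    ri <- paste(real$area, real$layer) == k
    si <- paste(shuf$area, shuf$layer) == k
    if (!any(ri) || !any(si)) {
      return(data.frame(group = k, n_real = sum(ri), n_shuffled = sum(si),
                        mean_real = NA_real_, mean_shuffled = NA_real_,
                        p_pooled = NA_real_, direction = NA_real_))
    }
    p <- rank_sum_test(real$weight[ri], shuf$weight[si])$p.value
    data.frame(
      group = k, n_real = sum(ri), n_shuffled = sum(si),
      mean_real = mean(real$weight[ri]),
      mean_shuffled = mean(shuf$weight[si]),
      p_pooled = p,
      direction = sign(mean(real$weight[ri]) - mean(shuf$weight[si]))
    )
  }))
  # calibrated iteration-level test: one pooled-mean weight per ensemble
  # member, two-sample rank-sum across members
  it_mean <- function(pool) {
    vapply(split(pool$weight, pool$iteration), mean, numeric(1))
  }
  mr <- it_mean(real); ms <- it_mean(shuf)
  p_iter <- if (length(mr) >= 2L && length(ms) >= 2L) {
    rank_sum_test(mr, ms)$p.value
  } else NA_real_
  p_pooled <- rank_sum_test(real$weight, shuf$weight)$p.value
  list(
    groups = groups,
    overall = list(
      p_value = p_iter, p_pooled = p_pooled,
      mean_real = mean(real$weight), mean_shuffled = mean(shuf$weight),
      direction = sign(mean(real$weight) - mean(shuf$weight))
    ),
    real = real, shuffled = shuf
  )
}

#' Median-split comparison of omission trial weights by behavior
#'
#' Splits omission trials at the within-session median of each behavioral
#' variable (running-wheel speed and pupil area) and compares the
#' omission-specific components' trial weights between the high and low
#' halves with the rank-sum test, pooling weights across omission-specific
#' components.
#'
#' @param model A `tca_model`.
#' @param trial_labels data.frame with `condition`, `wheel`, `pupil`.
#' @param alpha Classification significance level.
#' @param variables Behavioral columns to split on.
#' @return data.frame: `variable`, `p_value`, `n_high`, `n_low`,
#'   `mean_high`, `mean_low`, `n_components`. `p_value` is `NA` when no
#'   omission-specific component exists.
#' @export
behavior_median_split_compare <- function(model, trial_labels, alpha = 0.05,
                                          variables = c("wheel", "pupil")) {
  lab <- classify_components(model, trial_labels, alpha)
  comps <- lab$component[lab$specificity == "omission"]
  omi <- which(trial_labels$condition == "omission")
  W <- component_weights(model, "trial", scaled = TRUE)
  do.call(rbind, lapply(variables, function(v) {
    b <- trial_labels[[v]][omi]
    hi <- b > stats::median(b)
    if (sum(hi) < 2L || sum(!hi) < 2L) {
      stop(sprintf("fewer than 2 omission trials per %s half", v),
           call. = FALSE)
    }
    if (length(comps) == 0L) {
      return(data.frame(variable = v, p_value = NA_real_,
                        n_high = sum(hi), n_low = sum(!hi),
                        mean_high = NA_real_, mean_low = NA_real_,
                        n_components = 0L))
    }
    whigh <- as.vector(W[omi[hi], comps, drop = FALSE])
    wlow <- as.vector(W[omi[!hi], comps, drop = FALSE])
    data.frame(
      variable = v,
      p_value = rank_sum_test(whigh, wlow)$p.value,
      n_high = sum(hi), n_low = sum(!hi),
      mean_high = mean(whigh), mean_low = mean(wlow),
      n_components = length(comps)
    )
  }))
}
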