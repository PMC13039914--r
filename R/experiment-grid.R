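#' CAM groups for inclusion/exclusion experiments
#'
#' Groups of methodologically similar CAMs, each labelled with a single
#' letter. The shipped default grouping is:
#' A = HiResCAM + GradCAM-Elementwise, B = GradCAM + GradCAM++,
#' C = XGradCAM, D = AblationCAM + ScoreCAM, E = LayerCAM, F = FullGrad.
#' The eigen methods sit outside the default grid (their per-image cost is
#' disproportionate in large sweeps) but can be added via custom groups.
#'
#' @param label single-letter group label.
#' @param members character vector of method ids from [cam_methods()].
#' @return An object of class `cam_group`.
#' @export
cam_group <- function(label, members) {
  stopifnot(is.character(label), nchar(label) == 1L)
  bad <- setdiff(members, cam_methods())
  if (length(bad)) stop("unknown CAM methods: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(label = label, members = members), class = "cam_group")
}

#' @rdname cam_group
#' @export
default_cam_groups <- function() {
  list(cam_group("A", c("hirescam", "gradcam_elementwise")),
       cam_group("B", c("gradcam", "gradcampp")),
       cam_group("C", "xgradcam"),
       cam_group("D", c("ablationcam", "scorecam")),
       cam_group("E", "layercam"),
       cam_group("F", "fullgrad"))
}

#' Enumerate the binary inclusion/exclusion experiment grid
#'
#' For `n` disjoint CAM groups, builds all `2^n` binary codes; position `g`
#' of a code is `1` when group `g` is included, so `"100000"` with the
#' default grouping means "group A only". Each code resolves to the union of
#' its included groups' methods. The all-zero code is enumerated for count
#' fidelity but flagged unscorable (an empty consensus is undefined) and is
#' excluded from scoring and from the median used by [cre()].
#'
#' @param groups list of [cam_group()] objects (1 to 16 of them, disjoint).
#' @return An object of class `experiment_grid`: the groups plus one shell
#'   per code with its resolved method list.
#' @export
build_grid <- function(groups = default_cam_groups()) {
  n <- length(groups)
  if (n < 1 || n > 16) stop("between 1 and 16 groups supported", call. = FALSE)
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("group labels must be unique", call. = FALSE)
  members <- lapply(groups, `[[`, "members")
  if (anyDuplicated(unlist(members)))
    stop("groups must be disjoint", call. = FALSE)
  experiments <- lapply(0:(2^n - 1), function(b) {
    bits <- as.integer(intToBits(b))[n:1]  # leading bit = first group
    code <- paste(bits, collapse = "")
    meth <- unlist(members[bits == 1L], use.names = FALSE)
    list(code = code, methods = meth, scorable = any(bits == 1L))
  })
  structure(list(groups = groups, labels = labels, experiments = experiments),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("<experiment_grid: %d groups (%s), %d codes>\n",
              length(x$groups), paste(x$labels, collapse = ""),
              length(x$experiments)))
  invisible(x)
}

#' Compute a set of CAMs once for one (image, class, model) triple
#'
#' Convenience used by the grid runner and the high-level interface: runs
#' every requested method and returns the named list of [cam_result()]s,
#' invalid results included (filtering is the ensemble's job).
#'
#' @param model a [model_handle()].
#' @param image model input image.
#' @param class_index 1-based target class (default: model argmax).
#' @param methods method ids (default: all registered methods).
#' @param layer capturable layer (default: the model's last).
#' @param seed seed for `randomcam`.
#' @return Named list of `cam_result`.
#' @export
compute_cams <- function(model, image, class_index = NULL,
                         methods = cam_methods(), layer = NULL, seed = 1L) {
  if (is.null(class_index)) class_index <- predict_class(model, image)
  res <- lapply(methods, function(m)
    compute_cam(m, model, image, layer = layer, class_index = class_index,
                seed = seed))
  names(res) <- methods
  res
}

#' Run every experiment of an inclusion/exclusion grid
#'
#' For each scorable code: the valid maps of the included methods are
#' ensembled by consensus with an adaptive top-k search, and the best
#' threshold and its ROAD score are recorded. Individual experiment
#' failures (e.g. all included methods invalid) are recorded as unscorable;
#' they never abort the grid. Component CAMs are computed once and shared
#' across all codes.
#'
#' @param grid an [build_grid()] result.
#' @param cams named list of [cam_result()] covering every method in the
#'   grid; computed via [compute_cams()] when `NULL`.
#' @inheritParams compute_cams
#' @param k_grid candidate thresholds for the adaptive search.
#' @param config a [road_config()].
#' @return A data.frame with one row per code: `code`, `n_methods`,
#'   `best_k`, `road`, `scorable`; group labels are attached as the
#'   `"group_labels"` attribute.
#' @export
run_grid <- function(grid, model, image, class_index = NULL, cams = NULL,
                     k_grid = seq(5, 95, by = 5), config = road_config(),
                     layer = NULL, seed = 1L) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (is.null(class_index)) class_index <- predict_class(model, image)
  need <- unique(unlist(lapply(grid$experiments, `[[`, "methods")))
  if (is.null(cams))
    cams <- compute_cams(model, image, class_index, methods = need,
                         layer = layer, seed = seed)
  missing <- setdiff(need, names(cams))
  if (length(missing))
    stop("cams is missing methods: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(grid$experiments, function(ex) {
    out <- list(code = ex$code, n_methods = length(ex$methods),
                best_k = NA_real_, road = NA_real_, scorable = FALSE)
    if (!ex$scorable) return(out)
    ans <- tryCatch({
      valid <- drop_invalid(cams[ex$methods])
      ad <- adaptive_threshold_search(lapply(valid, `[[`, "map"),
                                      model, image, class_index,
                                      k_grid = k_grid, config = config)
      list(best_k = ad$best_k, road = ad$best_score)
    }, error = function(e) NULL)
    if (!is.null(ans)) {
      out$best_k <- ans$best_k; out$road <- ans$road; out$scorable <- TRUE
    }
    out
  })
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(code = r$code, n_methods = r$n_methods, best_k = r$best_k,
               road = r$road, scorable = r$scorable,
               stringsAsFactors = FALSE)))
  attr(df, "group_labels") <- grid$labels
  df
}

#' Cumulative Residual Effect of each CAM group
#'
#' Summarizes a grid of inclusion/exclusion experiments: each scored
#' experiment's residual is its ROAD score minus the median of all scored
#' experiments, and a group's CRE is the sum of the residuals of every
#' experiment that includes it. Positive CRE means including the group
#' tended to push scores above the experiment-wide median, negative that it
#' dragged them below. Because it is residual-based, CRE is invariant to
#' adding a constant to all scores, and CREs from several grids (different
#' images, classes or models) aggregate by simple group-wise summation.
#'
#' @param results a data.frame from [run_grid()] (or rbind of several),
#'   with columns `code`, `road`, `scorable`.
#' @param labels group labels, one per code position; defaults to the
#'   `"group_labels"` attribute of `results`.
#' @return An object of class `cre_report`: the per-group CRE vector, the
#'   median score and the number of scored experiments.
#' @export
cre <- function(results, labels = attr(results, "group_labels")) {
  sc <- results[results$scorable & is.finite(results$road), , drop = FALSE]
  if (nrow(sc) < 2)
    stop("CRE needs at least 2 scored experiments", call. = FALSE)
  n <- nchar(sc$code[1])
  if (is.null(labels)) labels <- LETTERS[seq_len(n)]
  med <- stats::median(sc$road)           # even count: mean of the middle two
  resid <- sc$road - med
  cre_g <- vapply(seq_len(n), function(g) {
    sum(resid[substr(sc$code, g, g) == "1"])
  }, numeric(1))
  names(cre_g) <- labels
  structure(list(cre = cre_g, median_score = med, n_scored = nrow(sc)),
            class = "cre_report")
}

#' @export
print.cre_report <- function(x, ...) {
  cat(sprintf("Cumulative Residual Effect (%d scored experiments, median ROAD %.4f)\n",
              x$n_scored, x$median_score))
  print(round(x$cre, 4))
  invisible(x)
}

#' @describeIn cre Bar-chart of per-group CRE values (force-plot style:
#'   positive bars push performance above the median, negative below).
#' @param x a `cre_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cre_report <- function(x, ...) {
  cols <- ifelse(x$cre >= 0, "#2c7fb8", "#d95f0e")
  graphics::barplot(x$cre, col = cols, border = NA,
                    ylab = "cumulative residual effect",
                    xlab = "CAM group", ...)
  graphics::abline(h = 0)
  invisible(x)
}
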