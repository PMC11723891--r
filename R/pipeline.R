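# Trait families analyzed by the study pipeline; each animal metric is
# paired with its own background counterpart, never cross-metric.
color_traits <- c("brightness", "saturation", "hue1", "hue2")
pattern_traits <- c("overall_contrast", "dominant_size_px", "diversity")
study_traits <- c(color_traits, pattern_traits)

#' Validate a taxon-level trait table against a tree
#'
#' Checks the contract every analysis stage relies on: a `taxon` column,
#' a `sex` column with both sexes, one row per taxon per sex, strictly
#' positive values in every ln-analyzed column present, and exact taxon
#' agreement with the tree's tips (after trimming whitespace).
#'
#' @param traits data frame of taxon-level traits.
#' @param tree an [ape::phylo] tree, or `NULL` to skip taxon matching.
#' @return the trait table, invisibly, if valid.
#' @export
validate_trait_table <- function(traits, tree = NULL) {
  traits <- as.data.frame(traits)
  if (!all(c("taxon", "sex") %in% names(traits)))
    stop("trait table needs `taxon` and `sex` columns")
  sexes <- unique(traits$sex)
  if (!all(c("female", "male") %in% sexes))
    stop("trait table must contain both sexes; found: ",
         paste(sexes, collapse = ", "))
  if (anyDuplicated(traits[, c("taxon", "sex")]))
    stop("more than one row per taxon x sex")
  num_cols <- intersect(c(study_traits, paste0("bg_", study_traits),
                          "pdt", "pwt"), names(traits))
  for (cl in num_cols) {
    v <- traits[[cl]]
    bad <- which(is.finite(v) & v <= 0)
    if (length(bad))
      stop("non-positive value in ln-scale column '", cl, "' (taxon ",
           paste(unique(traits$taxon[bad]), collapse = ", "), ")")
  }
  if (!is.null(tree)) {
    tips <- trimws(tree$tip.label)
    taxa <- unique(trimws(as.character(traits$taxon)))
    a <- setdiff(tips, taxa); b <- setdiff(taxa, tips)
    if (length(a) || length(b))
      stop("taxon mismatch; only in tree: [", paste(a, collapse = ", "),
           "]; only in table: [", paste(b, collapse = ", "), "]")
  }
  invisible(traits)
}

#' Color and pattern metrics for one calibrated image
#'
#' Computes the four color metrics for the animal and background regions
#' and, when the pixel scale is adequate, the three granularity
#' descriptors for both regions.
#'
#' @param image a [reflectance_image] with `animal` and `background`
#'   masks.
#' @param bank a [scale_bank][build_scale_bank].
#' @param min_px_per_mm pixel-scale threshold for pattern analysis.
#' @return one-row data frame with 14 metric columns (pattern columns are
#'   `NA` when the scale check fails or a region is constant) and an
#'   `exclusion` attribute (`NULL`, or a reason string).
#' @export
metrics_from_image <- function(image, bank = build_scale_bank(),
                               min_px_per_mm = 15) {
  row <- as.data.frame(as.list(c(
    region_color_metrics(image, "animal"),
    stats::setNames(region_color_metrics(image, "background"),
                    paste0("bg_", color_traits)))))
  pat_cols <- c(pattern_traits, paste0("bg_", pattern_traits))
  row[pat_cols] <- NA_real_
  exclusion <- NULL
  if (!check_pixel_scale(image$px_per_mm, min_px_per_mm)) {
    exclusion <- sprintf("pixel scale %.1f px/mm below %.1f; pattern metrics omitted",
                         image$px_per_mm, min_px_per_mm)
  } else {
    for (region in c("animal", "background")) {
      gs <- region_granularity(image, region, bank)
      pre <- if (region == "background") "bg_" else ""
      if (gs$undefined) {
        exclusion <- paste0("constant ", region,
                            " region; pattern descriptors undefined")
      } else {
        row[[paste0(pre, "overall_contrast")]] <- gs$overall_contrast
        row[[paste0(pre, "dominant_size_px")]] <- gs$dominant_size_px
        row[[paste0(pre, "diversity")]] <- gs$diversity
      }
    }
  }
  attr(row, "exclusion") <- exclusion
  row
}

#' Extract per-individual metrics from an image manifest
#'
#' The manifest lists one photographed individual per row with paths to
#' the raw image, the two region masks, and the gray-standard CSV
#' (columns `patch_id, mean_R, mean_G, mean_B, known_reflectance`), plus
#' `id`, `taxon`, `sex`, `px_per_mm`.  Unreadable records are skipped with
#' a per-record exclusion; the run continues.
#'
#' @param manifest data frame (or CSV path) with columns `id`, `taxon`,
#'   `sex`, `image`, `mask_animal`, `mask_background`, `standards`,
#'   `px_per_mm`.
#' @param bank a [scale_bank][build_scale_bank].
#' @param assume_srgb passed to [read_image_rgb()].
#' @return list with `rows` (per-individual metric table) and
#'   `exclusions` (data frame `id`, `reason`).
#' @export
extract_metrics <- function(manifest, bank = build_scale_bank(),
                            assume_srgb = FALSE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "taxon", "sex", "image", "mask_animal",
            "mask_background", "standards", "px_per_mm")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    res <- tryCatch({
      raw <- read_image_rgb(rec$image, assume_srgb = assume_srgb)
      std <- utils::read.csv(rec$standards, stringsAsFactors = FALSE)
      masks <- list(animal = read_mask(rec$mask_animal),
                    background = read_mask(rec$mask_background))
      img <- suppressWarnings(
        calibrate_from_gray_standards(raw, std,
                                      px_per_mm = rec$px_per_mm,
                                      masks = masks))
      metrics_from_image(img, bank)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <-
        data.frame(id = rec$id, reason = conditionMessage(res))
      next
    }
    if (!is.null(attr(res, "exclusion")))
      excl[[length(excl) + 1L]] <-
        data.frame(id = rec$id, reason = attr(res, "exclusion"))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(id = rec$id, taxon = rec$taxon, sex = rec$sex),
            res)
  }
  list(rows = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(id = character(), reason = character()))
}

#' Aggregate per-individual metrics to taxon x sex means
#'
#' @param rows per-individual table from [extract_metrics()]`$rows`.
#' @param method `"mean"` (default) or `"median"`.
#' @return taxon-level trait table (one row per taxon x sex).
#' @export
aggregate_to_taxa <- function(rows, method = c("mean", "median")) {
  method <- match.arg(method)
  rows <- as.data.frame(rows)
  if (!nrow(rows)) stop("no rows to aggregate")
  fun <- if (method == "mean") function(x) mean(x, na.rm = TRUE)
         else function(x) stats::median(x, na.rm = TRUE)
  num <- names(rows)[vapply(rows, is.numeric, logical(1))]
  num <- setdiff(num, "id")
  agg <- stats::aggregate(rows[num], by = rows[c("taxon", "sex")], FUN = fun)
  agg[order(agg$taxon, agg$sex), , drop = FALSE]
}

#' Run the full comparative study on a trait table and phylogeny
#'
#' For each sex and each trait, fits a PGLS of the ln animal metric on its
#' ln background counterpart plus ln precipitation of the driest (`pdt`)
#' and wettest (`pwt`) trimesters, with Pagel's lambda estimated by
#' maximum likelihood; adjusts all term-level p-values of the run by
#' Benjamini-Hochberg.  Then, per trait, computes phylogenetic independent
#' contrasts of the ln values for each sex, positivizes on the female
#' contrast, screens studentized-residual outliers at |3|, and fits the
#' through-origin major-axis regression of male on female contrasts with
#' its 95% confidence limits and slope = 1 test.
#'
#' @param traits taxon-level trait table (see [validate_trait_table()]).
#' @param tree matching [ape::phylo] tree.
#' @param lambda `NULL` to estimate per model, or a fixed value.
#' @param traits_to_run trait families to analyze (default all seven).
#' @param alpha significance level for the MA confidence limits.
#' @param filter_threshold studentized-residual cutoff (default 3).
#' @param out_dir optional directory; writes `table1_pgls.csv`,
#'   `table2_ma.csv` and `run_metadata.json` there.
#' @return object of class `study_report`: list with `pgls` (one row per
#'   model term), `ma` (one row per trait), and `metadata`.
#' @export
run_study <- function(traits, tree, lambda = NULL,
                      traits_to_run = study_traits, alpha = 0.05,
                      filter_threshold = 3, out_dir = NULL) {
  validate_trait_table(traits, tree)
  traits <- as.data.frame(traits)
  traits$taxon <- trimws(as.character(traits$taxon))

  pgls_rows <- list()
  for (sex in c("female", "male")) {
    sub <- traits[traits$sex == sex, , drop = FALSE]
    for (tr in traits_to_run) {
      bg <- paste0("bg_", tr)
      cols <- c(tr, bg, "pdt", "pwt")
      keep <- stats::complete.cases(sub[, cols])
      dat <- sub[keep, c("taxon", cols)]
      if (nrow(dat) < 6L) {
        warning("skipping ", sex, " ", tr, ": only ", nrow(dat),
                " complete taxa")
        next
      }
      sub_tree <- if (nrow(dat) < ape::Ntip(tree))
        ape::keep.tip(tree, dat$taxon) else tree
      fit <- pgls(dat, tr, c(bg, "pdt", "pwt"), sub_tree, lambda = lambda)
      tt <- fit$terms[fit$terms$term != "(Intercept)", , drop = FALSE]
      pgls_rows[[length(pgls_rows) + 1L]] <- data.frame(
        sex = sex, response = tr, term = tt$term, estimate = tt$estimate,
        t = tt$t, F = tt$F, multiple_r2 = fit$r.squared, p = tt$p,
        p_adjusted = NA_real_, lambda = fit$lambda,
        df_model = fit$df_model, df_residual = fit$df_residual,
        n = fit$n)
    }
  }
  if (!length(pgls_rows))
    stop("no PGLS model could be fitted (too few complete taxa)")
  pgls_tab <- do.call(rbind, pgls_rows)
  rownames(pgls_tab) <- NULL
  pgls_tab$p_adjusted <- bh_adjust(pgls_tab$p)

  ma_rows <- list()
  for (tr in traits_to_run) {
    f <- traits[traits$sex == "female", c("taxon", tr)]
    m <- traits[traits$sex == "male", c("taxon", tr)]
    mm <- merge(f, m, by = "taxon", suffixes = c("_f", "_m"))
    keep <- stats::complete.cases(mm[-1]) & mm[[2]] > 0 & mm[[3]] > 0
    mm <- mm[keep, ]
    if (nrow(mm) < 4L) {
      warning("skipping MA for ", tr, ": too few complete taxa")
      next
    }
    sub_tree <- if (nrow(mm) < ape::Ntip(tree))
      ape::keep.tip(tree, mm$taxon) else tree
    u <- independent_contrasts(sub_tree,
                               stats::setNames(log(mm[[2]]), mm$taxon))
    v <- independent_contrasts(sub_tree,
                               stats::setNames(log(mm[[3]]), mm$taxon))
    ma <- ma_analysis(u, v, b0 = 1, alpha = alpha,
                      filter_threshold = filter_threshold)
    ma_rows[[length(ma_rows) + 1L]] <- data.frame(
      trait = tr, beta = ma$beta, ucl = ma$ucl, lcl = ma$lcl, r2 = ma$r2,
      r_w = ma$wald_r, df = ma$df, p = ma$p_slope, n_used = ma$n_used,
      n_removed = length(ma$removed),
      independent_evolution = ma$degenerate)
  }
  ma_tab <- do.call(rbind, ma_rows)
  rownames(ma_tab) <- NULL

  report <- structure(list(
    pgls = pgls_tab, ma = ma_tab,
    metadata = list(
      lambda = if (is.null(lambda)) "ML" else lambda,
      bh_pool = "all term-level p-values of this run",
      alpha = alpha, filter_threshold = filter_threshold,
      traits = traits_to_run, n_taxa = length(unique(traits$taxon)))),
    class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$pgls, file.path(out_dir, "table1_pgls.csv"),
                     row.names = FALSE)
    utils::write.csv(report$ma, file.path(out_dir, "table2_ma.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report$metadata,
                         file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Comparative camouflage study report\n")
  cat("PGLS models (", length(unique(paste(x$pgls$sex, x$pgls$response))),
      " models, df ", x$pgls$df_model[1], ", ", x$pgls$df_residual[1],
      "):\n", sep = "")
  print(x$pgls, digits = 3)
  cat("\nMajor-axis regressions of male on female contrasts:\n")
  print(x$ma, digits = 3)
  invisible(x)
}
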