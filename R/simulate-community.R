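#' Default planted group effects for the synthetic two-group community
#'
#' The defaults emulate a smoker/nonsmoker contrast: *Lactobacillus* and
#' *Gardnerella* phages 10-fold enriched in the nonsmoker group,
#' *Prevotella* phages 2-fold enriched in smokers, lower expected richness
#' (35 vs 60 populations per sample) and lower evenness (per-sample
#' log-normal sigma 2.0 vs 0.8) in smokers.
#'
#' @param fold_changes Tibble with `host_genus` (or `genome_id`),
#'   `fold_change` (>= 1) and `enriched_group`.
#' @param richness Named numeric: expected per-sample richness per group.
#' @param sigma Named numeric: per-sample log-normal dispersion per group
#'   (larger = less even communities).
#' @return A list with elements `fold_changes`, `richness`, `sigma`.
#' @export
default_effect_spec <- function(
    fold_changes = tibble::tribble(
      ~host_genus,     ~fold_change, ~enriched_group,
      "Lactobacillus", 10,           "nonsmoker",
      "Gardnerella",   10,           "nonsmoker",
      "Prevotella",    2,            "smoker"
    ),
    richness = c(smoker = 35, nonsmoker = 60),
    sigma = c(smoker = 2.0, nonsmoker = 0.8)) {
  list(fold_changes = fold_changes, richness = richness, sigma = sigma)
}

#' A no-effect specification (both groups exchangeable)
#'
#' @param richness Common expected richness.
#' @param sigma Common log-normal dispersion.
#' @return Effect-spec list as in [default_effect_spec()].
#' @export
null_effect_spec <- function(richness = 50, sigma = 1) {
  list(fold_changes = tibble::tibble(host_genus = character(),
                                     fold_change = numeric(),
                                     enriched_group = character()),
       richness = c(smoker = richness, nonsmoker = richness),
       sigma = c(smoker = sigma, nonsmoker = sigma))
}

#' Design ground-truth two-group viral communities
#'
#' Per-sample relative abundances are drawn log-normally around shared
#' per-genome means, sparsified to the group's expected richness (an
#' occupancy draw: the present taxa are sampled uniformly without
#' replacement, independent of their conditional abundance), then planted
#' fold changes are applied to the enriched group and rows renormalised
#' to 1.  Group differences in the log-normal dispersion translate
#' directly into evenness differences because occupancy is
#' abundance-independent.
#'
#' With `deflate_planted = TRUE` (default) planted taxa have their shared
#' log-mean deflated by `log(fold_change)`, so enrichment restores them to
#' a typical abundance instead of letting them dominate the enriched
#' group: the planted contrast stays a rare-taxon fold change (expected
#' group mean ratio still equals the fold change) without distorting the
#' enriched group's evenness.  Set it to `FALSE` to plant dominance.
#'
#' @param reference Reference tibble from [generate_reference_db()].
#' @param group_sizes Named integer vector of group sizes (two groups, each
#'   >= 2); default `c(smoker = 20, nonsmoker = 10)`.
#' @param effect_spec See [default_effect_spec()].
#' @param deflate_planted Deflate planted taxa's baseline by their fold
#'   change (see Details).
#' @param seed Integer RNG seed.
#' @return An object of class `community_design`: list with `samples`
#'   (tibble of `sample_id`, `group`), `abundance` (wide tibble of true
#'   relative abundances), `planted` (resolved per-genome fold changes) and
#'   `reference`.
#' @export
design_communities <- function(reference,
                               group_sizes = c(smoker = 20, nonsmoker = 10),
                               effect_spec = default_effect_spec(),
                               deflate_planted = TRUE,
                               seed = 1) {
  if (length(group_sizes) != 2 || any(group_sizes < 2)) {
    stop("group_sizes must name two groups with >= 2 samples each",
         call. = FALSE)
  }
  fc <- effect_spec$fold_changes
  if (nrow(fc) > 0) {
    if (any(fc$fold_change < 1)) {
      stop("fold_change values must be >= 1", call. = FALSE)
    }
    if (!all(fc$enriched_group %in% names(group_sizes))) {
      stop("enriched_group must match a group name", call. = FALSE)
    }
  }
  groups <- names(group_sizes)
  if (!all(groups %in% names(effect_spec$richness)) ||
      !all(groups %in% names(effect_spec$sigma))) {
    stop("effect_spec richness/sigma must be named by group", call. = FALSE)
  }

  # resolve planted taxa to genome ids
  planted <- tibble::tibble(genome_id = character(), fold_change = numeric(),
                            enriched_group = character())
  if (nrow(fc) > 0) {
    key <- if ("genome_id" %in% names(fc)) "genome_id" else "host_genus"
    missing <- setdiff(fc[[key]], reference[[key]])
    if (length(missing) > 0) {
      stop("planted taxa absent from reference: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    planted <- dplyr::inner_join(reference[c("genome_id", "host_genus")],
                                 fc, by = key) %>%
      dplyr::select("genome_id", "fold_change", "enriched_group")
  }

  p <- nrow(reference)
  samples <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(sum(group_sizes))),
    group = rep(groups, group_sizes)
  )

  withr::with_seed(seed, {
    mu <- rnorm(p)  # shared per-genome log-mean
    if (deflate_planted && nrow(planted) > 0) {
      idx <- match(planted$genome_id, reference$genome_id)
      mu[idx] <- mu[idx] - log(planted$fold_change)
    }
    abund <- matrix(0, nrow(samples), p,
                    dimnames = list(samples$sample_id, reference$genome_id))
    for (i in seq_len(nrow(samples))) {
      g <- samples$group[i]
      x <- exp(mu + effect_spec$sigma[[g]] * rnorm(p))
      s <- rpois(1, effect_spec$richness[[g]])
      s <- max(2L, min(p, s))
      keep <- sample.int(p, s)
      y <- numeric(p)
      y[keep] <- x[keep]
      if (nrow(planted) > 0) {
        idx <- match(planted$genome_id, reference$genome_id)
        boost <- ifelse(planted$enriched_group == g, planted$fold_change, 1)
        y[idx] <- y[idx] * boost
      }
      abund[i, ] <- y / sum(y)
    }
    structure(list(samples = samples,
                   abundance = abund_tibble(abund),
                   planted = planted,
                   reference = reference),
              class = "community_design")
  })
}

#' @export
#' @method print community_design
print.community_design <- function(x, ...) {
  cat("<community_design> ", nrow(x$samples), " samples (",
      paste(sprintf("%s=%d", names(table(x$samples$group)),
                    as.integer(table(x$samples$group))), collapse = ", "),
      "), ", ncol(x$abundance) - 1, " genomes, ",
      nrow(x$planted), " planted fold changes\n", sep = "")
  invisible(x)
}

#' @export
tidy.community_design <- function(x, ...) {
  x$abundance %>%
    tidyr::pivot_longer(-"sample_id", names_to = "genome_id",
                        values_to = "true_abundance") %>%
    dplyr::left_join(x$samples, by = "sample_id")
}
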