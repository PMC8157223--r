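#' Score all embedding pairs as genuine or impostor
#'
#' All-against-all comparison: every unordered pair of embeddings gets a
#' distance score (Euclidean by default); a pair is genuine when both
#' embeddings come from the same subject, impostor otherwise. With k_i
#' embeddings per subject the genuine count is sum over subjects of
#' k_i (k_i - 1) / 2 and the total is n (n - 1) / 2.
#'
#' @param embs Tibble with a `subject_id` column and an `embedding`
#'   list-column (as returned by [embed_segments()]), or a numeric matrix of
#'   embeddings in rows with `subject_id` supplied separately.
#' @param subject_id Integer vector of identities (only when `embs` is a
#'   matrix).
#' @param metric `"euclidean"` (default) or `"cosine"` (1 minus cosine
#'   similarity).
#' @return Tibble of class `scored_pairs` with columns `i`, `j` (embedding
#'   indices), `distance` and `genuine`.
#' @export
score_all_pairs <- function(embs, subject_id = NULL,
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (is.data.frame(embs)) {
    subject_id <- embs$subject_id
    lens <- lengths(embs$embedding)
    if (length(unique(lens)) != 1) {
      abort("embedding dimension mismatch across rows")
    }
    M <- do.call(rbind, embs$embedding)
  } else {
    M <- as.matrix(embs)
    if (is.null(subject_id)) abort("subject_id required with a matrix input")
  }
  n <- nrow(M)
  if (n < 2) abort("need at least 2 embeddings to form pairs")
  d <- if (metric == "euclidean") {
    as.numeric(stats::dist(M))
  } else {
    nrm <- sqrt(rowSums(M^2))
    nrm[nrm == 0] <- 1
    S <- (M / nrm) %*% t(M / nrm)
    as.numeric(stats::as.dist(1 - S))
  }
  # dist() enumerates pairs column-wise over the lower triangle
  ii <- unlist(lapply(seq_len(n - 1), function(c) (c + 1):n))
  jj <- rep(seq_len(n - 1), times = (n - 1):1)
  out <- tibble(
    i = jj, j = ii, distance = d,
    genuine = subject_id[ii] == subject_id[jj]
  )
  class(out) <- c("scored_pairs", class(out))
  out
}

split_scores <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("distance", "genuine") %in% names(pairs)))
  list(genuine = pairs$distance[pairs$genuine],
       impostor = pairs$distance[!pairs$genuine])
}

#' Decidability (d-prime) of genuine vs impostor score distributions
#'
#' `d' = |mean_imp - mean_gen| / sqrt((var_imp + var_gen) / 2)` with sample
#' statistics; it measures how far apart the two score distributions sit,
#' invariant to a common affine rescaling of all scores.
#'
#' @param pairs A `scored_pairs` tibble (columns `distance`, `genuine`).
#' @return Dimensionless non-negative real.
#' @export
decidability <- function(pairs) {
  s <- split_scores(pairs)
  if (length(s$genuine) < 2 || length(s$impostor) < 2) {
    abort("need at least 2 scores in each class for decidability")
  }
  v <- (var(s$impostor) + var(s$genuine)) / 2
  if (v == 0) abort("zero variance in both score classes: decidability undefined")
  abs(mean(s$impostor) - mean(s$genuine)) / sqrt(v)
}

#' DET curve and equal error rate
#'
#' Sweeps the decision threshold over all distinct distances. At threshold t,
#' FAR is the fraction of impostor distances <= t (falsely accepted) and FRR
#' the fraction of genuine distances > t (falsely rejected). The EER is
#' (FAR + FRR) / 2 at the FAR = FRR crossing, located by linear interpolation
#' between the bracketing thresholds; when several thresholds tie, the
#' smallest is used.
#'
#' @param pairs A `scored_pairs` tibble.
#' @return Object of class `verification_result` with fields `thresholds`,
#'   `far`, `frr`, `eer`, `decidability`, `n_genuine`, `n_impostor`.
#' @export
det_and_eer <- function(pairs) {
  s <- split_scores(pairs)
  if (length(s$genuine) == 0 || length(s$impostor) == 0) {
    abort("need at least one genuine and one impostor pair")
  }
  thr <- sort(unique(pairs$distance))
  far <- stats::ecdf(s$impostor)(thr)
  frr <- 1 - stats::ecdf(s$genuine)(thr)
  diffs <- far - frr  # non-decreasing in threshold
  i <- which(diffs >= 0)[1]
  g <- (far + frr) / 2
  eer <- if (i == 1 || diffs[i] == 0) {
    g[i]
  } else {
    alpha <- (0 - diffs[i - 1]) / (diffs[i] - diffs[i - 1])
    g[i - 1] + alpha * (g[i] - g[i - 1])
  }
  dprime <- tryCatch(decidability(pairs), error = function(e) NA_real_)
  structure(
    list(thresholds = thr, far = far, frr = frr, eer = eer,
         decidability = dprime,
         n_genuine = length(s$genuine), n_impostor = length(s$impostor)),
    class = "verification_result"
  )
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf(
    "<verification_result> EER %.4f (%.2f%%), decidability %.3f; %d genuine / %d impostor pairs\n",
    x$eer, 100 * x$eer, x$decidability, x$n_genuine, x$n_impostor
  ))
  invisible(x)
}

#' @method tidy verification_result
#' @export
tidy.verification_result <- function(x, ...) {
  tibble(threshold = x$thresholds, far = x$far, frr = x$frr)
}

#' @method glance verification_result
#' @export
glance.verification_result <- function(x, ...) {
  tibble(eer = x$eer, decidability = x$decidability,
         n_genuine = x$n_genuine, n_impostor = x$n_impostor)
}

#' DET curve plot
#'
#' @param object A `verification_result`.
#' @param ... Ignored.
#' @return A ggplot of FRR against FAR with the EER marked.
#' @method autoplot verification_result
#' @export
autoplot.verification_result <- function(object, ...) {
  det <- tidy(object)
  ggplot2::ggplot(det, ggplot2::aes(x = .data$far, y = .data$frr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::annotate("point", x = object$eer, y = object$eer, colour = "red") +
    ggplot2::labs(
      x = "false acceptance rate", y = "false rejection rate",
      title = sprintf("DET curve (EER = %.2f%%)", 100 * object$eer)
    ) +
    ggplot2::theme_minimal()
}

#' Verify a set of embeddings end to end
#'
#' Convenience wrapper: [score_all_pairs()] then [det_and_eer()].
#'
#' @inheritParams score_all_pairs
#' @return A `verification_result`.
#' @export
verify_embeddings <- function(embs, subject_id = NULL,
                              metric = c("euclidean", "cosine")) {
  det_and_eer(score_all_pairs(embs, subject_id, metric))
}

#' Write a verification result to disk
#'
#' Emits `<stem>.json` with eer, decidability and pair counts, and optionally
#' `<stem>_det.tsv` with the threshold/FAR/FRR table.
#'
#' @param result A `verification_result`.
#' @param stem Output path stem.
#' @param det_table Also write the DET table as TSV.
#' @return Invisibly, the JSON path.
#' @export
write_verification <- function(result, stem, det_table = TRUE) {
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(
    list(eer = result$eer, decidability = result$decidability,
         n_genuine = result$n_genuine, n_impostor = result$n_impostor),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (det_table) {
    utils::write.table(tidy(result), paste0(stem, "_det.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
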