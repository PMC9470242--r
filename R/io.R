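fmt_num <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (c in which(num)) df[[c]] <- fmt_num(df[[c]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a study dataset to a directory of tabular text files
#'
#' Writes \code{tacs.tsv} (subject, region, frame_start, frame_end, value),
#' \code{covariates.tsv}, \code{aif_params.tsv}, \code{blood_means.tsv}
#' (per-subject whole-blood frame means), and \code{truth.json} when the
#' study carries a simulation truth block. Deterministic column order,
#' numbers at 6 significant digits, UTF-8.
#'
#' @param study A \code{study_dataset}.
#' @param path Output directory (created if absent).
#' @return The path, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv(study$tacs, file.path(path, "tacs.tsv"))
  write_tsv(study$covariates, file.path(path, "covariates.tsv"))
  aifs <- do.call(rbind, lapply(names(study$aifs), function(s) {
    a <- study$aifs[[s]]
    data.frame(subject = s, t0 = a$t0, b = a$b, tp = a$tp,
               A1 = a$A[1], A2 = a$A[2], A3 = a$A[3],
               lambda1 = a$lambda[1], lambda2 = a$lambda[2],
               lambda3 = a$lambda[3], stringsAsFactors = FALSE)
  }))
  write_tsv(aifs, file.path(path, "aif_params.tsv"))
  sched <- study$schedule
  bm <- do.call(rbind, lapply(rownames(study$blood), function(s)
    data.frame(subject = s, frame_start = sched$start, frame_end = sched$end,
               value = study$blood[s, ], stringsAsFactors = FALSE)))
  write_tsv(bm, file.path(path, "blood_means.tsv"))
  if (!is.null(study$truth)) {
    tr <- study$truth
    truth_out <- list(
      config = list(n_per_group = tr$config$n_per_group,
                    effect_log_bpnd = tr$config$effect_log_bpnd,
                    error_scale = tr$config$error_scale,
                    correlations_on = tr$config$correlations_on,
                    seed = tr$config$seed),
      regions = tr$regions,
      tacs = tr$tacs)
    jsonlite::write_json(truth_out, file.path(path, "truth.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "columns")
  }
  invisible(path)
}

#' Read a study dataset from a directory
#'
#' Reads and validates the files written by \code{\link{write_study}}:
#' every (subject, region) pair must have a consistent, non-overlapping
#' frame set (TACs missing frames relative to the modal schedule are
#' allowed and flagged in the \code{missing_frames} attribute), and the
#' covariate table must cover every subject.
#'
#' @param path Directory containing \code{tacs.tsv}, \code{covariates.tsv},
#'   \code{aif_params.tsv} and \code{blood_means.tsv}.
#' @return A \code{study_dataset}.
#' @export
read_study <- function(path) {
  need <- c("tacs.tsv", "covariates.tsv", "aif_params.tsv", "blood_means.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("missing study file(s): ", paste(missing, collapse = ", "))
  rd <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  tacs <- rd("tacs.tsv"); covariates <- rd("covariates.tsv")
  aift <- rd("aif_params.tsv"); bm <- rd("blood_means.tsv")

  for (col in c("subject", "region", "frame_start", "frame_end", "value"))
    if (!col %in% names(tacs)) stop("tacs.tsv lacks column '", col, "'")
  absent <- setdiff(unique(tacs$subject), covariates$subject)
  if (length(absent))
    stop("subject(s) absent from covariates.tsv: ", paste(absent, collapse = ", "))

  # modal frame set defines the schedule
  key <- paste(fmt_num(tacs$frame_start), fmt_num(tacs$frame_end))
  frames <- unique(tacs[, c("frame_start", "frame_end")])
  frames <- frames[order(frames$frame_start), ]
  if (any(diff(frames$frame_start) <= 0) ||
      any(frames$frame_start[-1] < frames$frame_end[-nrow(frames)] - 1e-9))
    stop("overlapping or inconsistent frames in tacs.tsv")
  sched <- frame_schedule(frames$frame_start, frames$frame_end)
  nI <- length(sched$start)

  tac_tab <- unique(tacs[, c("subject", "region")])
  counts <- table(paste(tacs$subject, tacs$region))
  incomplete <- names(counts)[counts < nI]

  aifs <- stats::setNames(lapply(seq_len(nrow(aift)), function(i)
    aif_parameters(aift$t0[i], aift$b[i], aift$tp[i],
                   A = c(aift$A1[i], aift$A2[i], aift$A3[i]),
                   lambda = c(aift$lambda1[i], aift$lambda2[i], aift$lambda3[i]))),
    aift$subject)
  subs <- unique(bm$subject)
  blood <- t(vapply(subs, function(s) bm$value[bm$subject == s], numeric(nI)))
  rownames(blood) <- subs

  truth <- NULL
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- list(config = tj$config, regions = tj$regions,
                  tacs = as.data.frame(tj$tacs, stringsAsFactors = FALSE))
  }
  out <- structure(list(tacs = tacs, schedule = sched, aifs = aifs,
                        blood = blood, covariates = covariates,
                        truth = truth),
                   class = "study_dataset")
  attr(out, "missing_frames") <- incomplete
  out
}
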