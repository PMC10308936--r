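# Post-search label-free proteome comparison: within-sample abundance
# ranking, replicate rank summaries, not-detected/exclusive calls, and
# a report mirroring the published table layout. Peptide-spectrum
# matching, protein inference and FDR estimation are upstream and out
# of scope; the FDR confidence category is carried through as metadata.

#' Construct a protein abundance table
#'
#' @param abundance numeric matrix, proteins (rows, named by locus tag)
#'   x samples (columns, named). `NA` means not detected (ND); present
#'   abundances must be > 0 (a zero abundance is invalid input, not ND).
#' @param psm optional integer matrix of peptide-spectrum-match counts,
#'   same shape/dimnames.
#' @param confidence optional character matrix of FDR confidence
#'   categories ("High"/"Medium"/"Low"; `NA`/"ND" where not detected).
#' @param protein_name optional character vector of protein names, one
#'   per row.
#' @return object of class `protein_table`.
#' @export
protein_table <- function(abundance, psm = NULL, confidence = NULL,
                          protein_name = NULL) {
  if (!is.matrix(abundance) || is.null(rownames(abundance)) ||
      is.null(colnames(abundance))) {
    stop("`abundance` must be a matrix with locus-tag rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(abundance))) {
    stop("locus tags must be unique", call. = FALSE)
  }
  if (any(abundance <= 0, na.rm = TRUE)) {
    stop("present abundances must be > 0 (use NA for not-detected)",
         call. = FALSE)
  }
  check_shape <- function(m, what) {
    if (!is.null(m) && !identical(dim(m), dim(abundance))) {
      stop(sprintf("`%s` must match the abundance matrix shape", what),
           call. = FALSE)
    }
  }
  check_shape(psm, "psm"); check_shape(confidence, "confidence")
  if (!is.null(protein_name) && length(protein_name) != nrow(abundance)) {
    stop("`protein_name` must have one entry per protein", call. = FALSE)
  }
  structure(list(abundance = abundance, psm = psm, confidence = confidence,
                 protein_name = protein_name,
                 samples = colnames(abundance),
                 locus_tags = rownames(abundance)),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("<protein_table> %d proteins x %d samples (%s)\n",
              length(x$locus_tags), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Rank proteins within one sample by abundance
#'
#' The most abundant protein receives rank 1. Ties receive the average
#' of the tied rank positions by default (`"competition"` gives the
#' minimum instead). Not-detected proteins must be excluded beforehand.
#'
#' @param abundances named numeric vector of present-only abundances.
#' @param ties `"average"` (default) or `"competition"`.
#' @return named numeric vector of ranks (empty input -> empty result).
#' @export
rank_within_sample <- function(abundances, ties = c("average", "competition")) {
  ties <- match.arg(ties)
  if (length(abundances) == 0L) return(setNames(numeric(0), character(0)))
  if (anyNA(abundances)) {
    stop("ND entries must be removed before ranking", call. = FALSE)
  }
  rank(-abundances, ties.method = if (ties == "average") "average" else "min")
}

# per-sample rank matrix (NA where ND)
rank_matrix <- function(table, ties = "average") {
  stopifnot(inherits(table, "protein_table"))
  out <- table$abundance
  out[] <- NA_real_
  for (s in table$samples) {
    present <- !is.na(table$abundance[, s])
    out[present, s] <- rank_within_sample(table$abundance[present, s], ties)
  }
  out
}

#' Summarize per-replicate ranks by condition
#'
#' Per protein and condition: mean and spread of the within-sample
#' ranks over the replicates where the protein was detected. A protein
#' absent from every replicate of a condition is ND (`mean_rank = NA`).
#' With a single detected replicate the spread is reported as 0 and
#' `single_replicate` is flagged.
#'
#' @param table a [protein_table()].
#' @param condition_map named character vector, sample -> condition.
#' @param ties tie policy passed to [rank_within_sample()].
#' @param sd_method `"sample"` (sample SD, default) or `"half_range"`
#'   ((max - min)/2; for n = 2 the two differ by sqrt(2)).
#' @return tibble with `locus_tag`, `condition`, `detected_replicates`,
#'   `mean_rank`, `sd_rank`, `single_replicate`; the per-condition
#'   replicate counts are attached as attribute `n_replicates`.
#' @export
summarize_ranks <- function(table, condition_map, ties = "average",
                            sd_method = c("sample", "half_range")) {
  stopifnot(inherits(table, "protein_table"))
  sd_method <- match.arg(sd_method)
  unknown <- setdiff(names(condition_map), table$samples)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown sample(s) in condition_map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ranks <- rank_matrix(table, ties)
  conditions <- unique(unname(condition_map))
  rows <- list()
  for (cond in conditions) {
    smp <- names(condition_map)[condition_map == cond]
    sub <- ranks[, smp, drop = FALSE]
    det <- rowSums(!is.na(sub))
    mr <- rowMeans(sub, na.rm = TRUE)
    mr[det == 0L] <- NA_real_
    sdr <- apply(sub, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) <= 1L) return(0)
      if (sd_method == "sample") sd(v) else (max(v) - min(v)) / 2
    })
    sdr[det == 0L] <- NA_real_
    rows[[cond]] <- tibble::tibble(
      locus_tag = table$locus_tags, condition = cond,
      detected_replicates = as.integer(unname(det)),
      mean_rank = unname(mr), sd_rank = unname(sdr),
      single_replicate = unname(det == 1L)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_replicates") <- vapply(
    conditions, function(cond) sum(condition_map == cond), integer(1))
  out
}

#' Proteins detected exclusively in one condition
#'
#' Proteins detected in at least `min_detected` replicates of
#' `condition_a` and in none of `condition_b`. The strict default
#' requires detection in every replicate of `condition_a`.
#'
#' @param summaries output of [summarize_ranks()].
#' @param condition_a,condition_b condition labels.
#' @param min_detected minimum detected replicates in `condition_a`
#'   (default: all of them).
#' @return sorted character vector of locus tags.
#' @export
exclusive_proteins <- function(summaries, condition_a, condition_b,
                               min_detected = NULL) {
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% summaries$condition) {
      stop(sprintf("condition '%s' absent from summaries", cond), call. = FALSE)
    }
  }
  if (is.null(min_detected)) {
    nrep <- attr(summaries, "n_replicates")
    min_detected <- if (!is.null(nrep) && condition_a %in% names(nrep)) {
      nrep[[condition_a]]
    } else {
      max(summaries$detected_replicates[summaries$condition == condition_a])
    }
  }
  a <- summaries[summaries$condition == condition_a, ]
  b <- summaries[summaries$condition == condition_b, ]
  b_det <- setNames(b$detected_replicates, b$locus_tag)
  hits <- a$locus_tag[a$detected_replicates >= min_detected &
                        b_det[a$locus_tag] == 0L]
  sort(hits)
}

#' Divide each sample by a reference protein's abundance
#'
#' Optional internal-standard normalization (e.g. to a spiked GAPDH).
#' Ranking is invariant under this per-sample scaling; it only affects
#' exported abundance values.
#'
#' @param table a [protein_table()].
#' @param reference_locus locus tag of the reference protein; must be
#'   detected in every sample.
#' @export
normalize_to_reference <- function(table, reference_locus) {
  stopifnot(inherits(table, "protein_table"))
  if (!reference_locus %in% table$locus_tags) {
    stop(sprintf("reference protein '%s' not in table", reference_locus),
         call. = FALSE)
  }
  ref <- table$abundance[reference_locus, ]
  if (anyNA(ref)) {
    stop("reference protein must be detected in every sample", call. = FALSE)
  }
  table$abundance <- sweep(table$abundance, 2, ref, `/`)
  table
}

#' Generate a synthetic two-condition protein table with planted
#' condition-exclusive proteins
#'
#' Abundances are i.i.d. log-normal per sample; `n_exclusive` randomly
#' chosen proteins are detected in every replicate of the first
#' condition and in none of the second (the planted exclusive set).
#' With `dropout_rate = 0` (the default, noise-free generator) those
#' are the only ND cells, so the planted set is recovered exactly by
#' [exclusive_proteins()].
#'
#' @param n_proteins,n_exclusive,n_replicates counts
#'   (`n_exclusive <= n_proteins`).
#' @param meanlog,sdlog log-normal abundance parameters (defaults
#'   log(1e6) and 2, a wide dynamic range typical of label-free data).
#' @param dropout_rate per-cell probability of ND among non-exclusive
#'   proteins (default 0).
#' @param conditions length-2 character vector of condition labels.
#' @param seed integer; same seed -> identical tables.
#' @return list with `table` (a [protein_table()]), `exclusive`
#'   (planted locus tags, sorted) and `condition_map`.
#' @export
synthesize_protein_tables <- function(n_proteins = 2300, n_exclusive = 25,
                                      n_replicates = 2,
                                      meanlog = log(1e6), sdlog = 2,
                                      dropout_rate = 0,
                                      conditions = c("w/o N", "w/ N"),
                                      seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_exclusive <- as.integer(n_exclusive)
  n_replicates <- as.integer(n_replicates)
  if (n_proteins < 1L || n_replicates < 1L || n_exclusive < 0L) {
    stop("invalid counts", call. = FALSE)
  }
  if (n_exclusive > n_proteins) {
    stop("`n_exclusive` cannot exceed `n_proteins`", call. = FALSE)
  }
  if (length(conditions) != 2L) stop("need exactly two conditions", call. = FALSE)
  withr::with_seed(seed, {
    locus <- sprintf("SYN_%05d", seq_len(n_proteins))
    samples <- as.vector(outer(paste0("M", seq_len(n_replicates)), conditions,
                               paste))
    condition_map <- setNames(rep(conditions, each = n_replicates), samples)
    ab <- matrix(rlnorm(n_proteins * length(samples), meanlog, sdlog),
                 nrow = n_proteins, dimnames = list(locus, samples))
    exclusive <- sort(sample(locus, n_exclusive))
    cond_b_samples <- names(condition_map)[condition_map == conditions[2]]
    ab[exclusive, cond_b_samples] <- NA_real_
    if (dropout_rate > 0) {
      drop <- matrix(runif(length(ab)) < dropout_rate, nrow = n_proteins)
      drop[exclusive, ] <- FALSE
      ab[drop] <- NA_real_
    }
    psm <- matrix(NA_integer_, n_proteins, length(samples),
                  dimnames = dimnames(ab))
    present <- !is.na(ab)
    psm[present] <- 1L + rpois(sum(present), pmax(log10(ab[present]), 0))
    conf <- matrix(NA_character_, n_proteins, length(samples),
                   dimnames = dimnames(ab))
    conf[present] <- ifelse(psm[present] >= 2L, "High", "Medium")
    tab <- protein_table(ab, psm = psm, confidence = conf,
                         protein_name = paste("synthetic protein",
                                              seq_len(n_proteins)))
    list(table = tab, exclusive = exclusive, condition_map = condition_map)
  })
}

#' Report table mirroring the published layout
#'
#' One row per protein: locus tag, name, "mean +/- SD" rank string per
#' condition (ND when undetected), and per-sample PSM and confidence
#' columns.
#'
#' @param table a [protein_table()].
#' @param condition_map named character vector, sample -> condition.
#' @param ... passed to [summarize_ranks()].
#' @export
ranking_report <- function(table, condition_map, ...) {
  summaries <- summarize_ranks(table, condition_map, ...)
  fmt <- function(m, s) {
    ifelse(is.na(m), "ND", sprintf("%.1f ± %.1f", m, s))
  }
  out <- tibble::tibble(
    locus_tag = table$locus_tags,
    protein_name = table$protein_name %||% NA_character_
  )
  for (cond in unique(summaries$condition)) {
    sub <- summaries[summaries$condition == cond, ]
    sub <- sub[match(out$locus_tag, sub$locus_tag), ]
    out[[paste0("rank_", cond)]] <- fmt(sub$mean_rank, sub$sd_rank)
  }
  for (s in table$samples) {
    if (!is.null(table$psm)) out[[paste0("psm_", s)]] <- table$psm[, s]
    if (!is.null(table$confidence)) {
      conf <- table$confidence[, s]
      out[[paste0("confidence_", s)]] <- ifelse(is.na(conf), "ND", conf)
    }
  }
  out
}

#' Write/read a protein table as wide CSV
#'
#' Columns: `locus_tag`, `protein_name`, then `abundance_<sample>`,
#' `psm_<sample>`, `confidence_<sample>` per sample; empty cells are ND.
#'
#' @param table a [protein_table()].
#' @param path CSV path.
#' @export
write_protein_table <- function(table, path) {
  stopifnot(inherits(table, "protein_table"))
  out <- tibble::tibble(locus_tag = table$locus_tags,
                        protein_name = table$protein_name %||% NA_character_)
  for (s in table$samples) {
    out[[paste0("abundance_", s)]] <- table$abundance[, s]
    if (!is.null(table$psm)) out[[paste0("psm_", s)]] <- table$psm[, s]
    if (!is.null(table$confidence)) {
      out[[paste0("confidence_", s)]] <- table$confidence[, s]
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_protein_table
#' @export
read_protein_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = c("", "ND"))
  ab_cols <- grep("^abundance_", names(df), value = TRUE)
  samples <- sub("^abundance_", "", ab_cols)
  grab <- function(prefix, mode) {
    cols <- paste0(prefix, samples)
    if (!all(cols %in% names(df))) return(NULL)
    m <- as.matrix(df[, cols])
    storage.mode(m) <- mode
    dimnames(m) <- list(df$locus_tag, samples)
    m
  }
  protein_table(grab("abundance_", "double"),
                psm = grab("psm_", "integer"),
                confidence = grab("confidence_", "character"),
                protein_name = if ("protein_name" %in% names(df)) {
                  df$protein_name
                })
}
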