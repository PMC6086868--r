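#' Classifier parameters
#'
#' Tunable knobs of the two-pass bits-per-base classifier. Pass-2 weights
#' damp each alignment's per-base score by its accuracy relative to the
#' per-position global top: `w(r) = r^p` for nucleotide records and
#' `w(r) = r^(p^p)` for translated records (default `p = 3`, so nucleotide
#' mismatches are penalized polynomially and protein mismatches far more
#' harshly — protein sequence is the more conserved signal, so disagreement
#' there is stronger evidence against a taxon). The candidate radius and
#' the LCA majority threshold are dynamic: weak best hits widen the radius,
#' large total volumes lower the majority required.
#'
#' @param p Nucleotide weight exponent; the translated exponent is `p^p`.
#' @param b_max Bits per base of a perfect nucleotide self-alignment
#'   (information ceiling, default 2.0).
#' @param radius_min,radius_max Bounds of the dynamic candidate radius.
#' @param lca_base_majority Majority floor (default 0.5).
#' @param lca_excess Extra majority required as volume vanishes (default
#'   0.45; the threshold is capped at 0.95).
#' @param lca_volume_scale Volume scale `V0` (bits) of the hyperbolic decay
#'   (default 2000).
#' @param min_contig_bits Contigs whose best pass-1 score is below this are
#'   filtered as low-information (default 300).
#' @param min_taxon_bits Taxa whose aggregate pass-1 bits across contigs
#'   fall below this are suppressed from the report (default 1000).
#' @param viral_base_fraction A contig is filtered when more than this
#'   fraction of its aligned bases is topped by non-viral taxa (default
#'   0.5).
#' @param viral_taxid Taxid of the viral superkingdom (default 10239).
#' @param unclassified_min_len Minimum length for an unclassifiable contig
#'   to be listed in the report's unclassified section (default 500).
#' @param ranks Rank ladder for the rank-wise LCA walk.
#' @return Named list of class `classifier_params`.
#' @export
classifier_params <- function(p = 3, b_max = 2.0,
                              radius_min = 0.02, radius_max = 0.25,
                              lca_base_majority = 0.5, lca_excess = 0.45,
                              lca_volume_scale = 2000,
                              min_contig_bits = 300, min_taxon_bits = 1000,
                              viral_base_fraction = 0.5,
                              viral_taxid = 10239L,
                              unclassified_min_len = 500L,
                              ranks = default_ranks()) {
  stopifnot(p >= 1, b_max > 0,
            radius_min > 0, radius_min <= radius_max, radius_max < 1,
            min_contig_bits > 0, min_taxon_bits > 0)
  structure(
    list(p = p, p_aa = p^p, b_max = b_max,
         radius_min = radius_min, radius_max = radius_max,
         lca_base_majority = lca_base_majority, lca_excess = lca_excess,
         lca_volume_scale = lca_volume_scale,
         min_contig_bits = min_contig_bits, min_taxon_bits = min_taxon_bits,
         viral_base_fraction = viral_base_fraction,
         viral_taxid = as.integer(viral_taxid),
         unclassified_min_len = as.integer(unclassified_min_len),
         ranks = ranks),
    class = "classifier_params"
  )
}

#' Pass 1: per-position best bits-per-base per taxon
#'
#' Each alignment record contributes its bit score divided by its aligned
#' query length as a flat per-base score over the query span it covers; per
#' position and per taxon the maximum such score is kept. The per-taxon
#' pass-1 score is the sum of that taxon's per-position tops — the taxon's
#' best potential alignment, independent of subject contiguity. Nucleotide
#' and translated records share the same query coordinate space and are
#' profiled together.
#'
#' @param records Alignment tibble for one contig (the contig as query).
#' @param L Contig length.
#' @param contig_id Contig identifier (defaults to the records' query id).
#' @return A `pass1_profile`: list with `contig_id`, `length`,
#'   `top_per_taxon` (taxa x L matrix), `global_top` (length-L vector),
#'   `pass1_score` (named vector), `taxids`.
#' @export
pass1 <- function(records, L, contig_id = NULL) {
  L <- as.integer(L)
  if (is.null(contig_id)) {
    contig_id <- if (nrow(records) > 0) records$query_id[1] else ""
  }
  if (nrow(records) > 0 &&
      (any(records$q_start < 1L) || any(records$q_end > L))) {
    stop("alignment record outside contig [1, ", L, "]", call. = FALSE)
  }
  taxids <- sort(unique(records$subject_taxid))
  top <- matrix(0, nrow = length(taxids), ncol = L,
                dimnames = list(taxids, NULL))
  if (nrow(records) > 0) {
    s <- records$bits / records$aligned_len_q
    ti <- match(records$subject_taxid, taxids)
    for (i in seq_len(nrow(records))) {
      span <- records$q_start[i]:records$q_end[i]
      top[ti[i], span] <- pmax(top[ti[i], span], s[i])
    }
  }
  global_top <- if (length(taxids) > 0) Reduce(pmax, asplit(top, 1)) else
    numeric(L)
  structure(
    list(contig_id = contig_id, length = L, top_per_taxon = top,
         global_top = as.numeric(global_top),
         pass1_score = stats::setNames(rowSums(top), rownames(top)),
         taxids = taxids),
    class = "pass1_profile"
  )
}

#' Pass 2: relative-accuracy-weighted volume per taxon
#'
#' With the global per-position tops known, every record's per-base score
#' `s` is weighted by its accuracy relative to the top, `r = s / top[p]`,
#' through the damping `w(r)` (see [classifier_params()]); the contribution
#' at each covered position is `s * w(r)`. Contributions are summed over
#' positions and over database entries per taxon — so, unlike pass 1, many
#' consistent entries of one taxon accumulate "volume".
#'
#' @param records Alignment tibble for the contig.
#' @param profile The contig's [pass1()] profile.
#' @param params [classifier_params()].
#' @return A `pass2_volume`: list with `volume` (named numeric by taxid) and
#'   `per_entry` (audit tibble: subject_id, subject_taxid, kind, volume).
#' @export
pass2 <- function(records, profile, params = classifier_params()) {
  g <- profile$global_top
  entry_vol <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    span <- records$q_start[i]:records$q_end[i]
    s <- records$bits[i] / records$aligned_len_q[i]
    gt <- g[span]
    if (any(gt <= 0)) {
      stop("global top is zero inside a covered span: pass 1 inconsistency",
           call. = FALSE)
    }
    r <- pmin(s / gt, 1)
    expo <- if (records$kind[i] == "aa") params$p_aa else params$p
    entry_vol[i] <- sum(s * r^expo)
  }
  per_entry <- tibble::tibble(
    subject_id = records$subject_id,
    subject_taxid = records$subject_taxid,
    kind = records$kind,
    volume = entry_vol
  ) |>
    dplyr::group_by(.data$subject_id, .data$subject_taxid, .data$kind) |>
    dplyr::summarise(volume = sum(.data$volume), .groups = "drop")
  vol <- tapply(entry_vol, records$subject_taxid, sum)
  structure(
    list(volume = stats::setNames(as.numeric(vol), names(vol)),
         per_entry = per_entry),
    class = "pass2_volume"
  )
}

#' Viral-superkingdom filter
#'
#' A contig fails when its top pass-1 taxon is not in the viral
#' superkingdom, or when more than `viral_base_fraction` of its aligned
#' positions have their global top achieved only by non-viral taxa (a tie
#' at a position counts as viral).
#'
#' @param profile A [pass1()] profile.
#' @param tree A `taxonomy`.
#' @param params [classifier_params()].
#' @return List: `pass` (logical), `reason`, `top_taxid`,
#'   `nonviral_fraction`.
#' @export
viral_filter <- function(profile, tree, params = classifier_params()) {
  sc <- profile$pass1_score
  if (length(sc) == 0) {
    return(list(pass = FALSE, reason = "no alignments",
                top_taxid = NA_integer_, nonviral_fraction = NA_real_))
  }
  viral <- vapply(profile$taxids, function(t)
    is_descendant(tree, t, params$viral_taxid), TRUE)
  # exact top-score ties resolve in favor of a viral taxon
  tied <- which(sc >= max(sc) - 1e-12)
  tied_viral <- tied[viral[tied]]
  top_taxid <- if (length(tied_viral) > 0)
    as.integer(names(sc)[tied_viral[1]]) else as.integer(names(sc)[tied[1]])
  if (!viral[match(top_taxid, profile$taxids)]) {
    return(list(pass = FALSE,
                reason = paste0("top pass-1 taxon ", top_taxid,
                                " outside the viral superkingdom"),
                top_taxid = top_taxid, nonviral_fraction = NA_real_))
  }
  aligned <- profile$global_top > 0
  if (any(viral)) {
    viral_top <- Reduce(pmax, asplit(
      profile$top_per_taxon[viral, , drop = FALSE], 1))
  } else {
    viral_top <- numeric(profile$length)
  }
  eps <- 1e-12
  nonviral_topped <- aligned & (viral_top < profile$global_top - eps)
  frac <- sum(nonviral_topped) / max(1L, sum(aligned))
  if (frac > params$viral_base_fraction) {
    return(list(pass = FALSE,
                reason = sprintf(
                  "%.1f%% of aligning bases topped by non-viral taxa (> %.0f%%)",
                  100 * frac, 100 * params$viral_base_fraction),
                top_taxid = top_taxid, nonviral_fraction = frac))
  }
  list(pass = TRUE, reason = "viral", top_taxid = top_taxid,
       nonviral_fraction = frac)
}

#' Dynamic-radius candidate selection
#'
#' The radius below the best pass-1 score within which taxa enter the LCA
#' widens as the best hit weakens relative to a hypothetical perfect
#' self-alignment (`L * b_max` bits): with quality
#' `q = pass1_best / (L * b_max)` clamped to `[0, 1]`, the radius fraction
#' is `radius_min + (radius_max - radius_min) * (1 - q)` and candidates are
#' all taxa with `pass1_score >= (1 - radius) * pass1_best`.
#'
#' @param profile A [pass1()] profile.
#' @param params [classifier_params()].
#' @return Integer vector of candidate taxids (ascending).
#' @export
candidate_set <- function(profile, params = classifier_params()) {
  sc <- profile$pass1_score
  best <- max(sc)
  q <- min(1, max(0, best / (profile$length * params$b_max)))
  radius <- params$radius_min + (params$radius_max - params$radius_min) * (1 - q)
  sort(as.integer(names(sc)[sc >= (1 - radius) * best]))
}

#' Dynamic majority threshold of the LCA engine
#'
#' `m(V) = lca_base_majority + lca_excess / (1 + V / V0)`, capped at 0.95:
#' strictly decreasing in the total volume `V`, so poorly represented taxa
#' need a commanding majority while well represented ones need only a
#' slight one.
#'
#' @param V Total candidate volume (bits).
#' @param params [classifier_params()].
#' @return The required majority fraction.
#' @export
majority_threshold <- function(V, params = classifier_params()) {
  min(0.95, params$lca_base_majority +
        params$lca_excess / (1 + V / params$lca_volume_scale))
}

#' Volume-weighted rank-wise LCA
#'
#' Walks the rank ladder leaf to root (unranked clades are transparent). At
#' each rank the candidate volumes are projected onto their ancestors at
#' that rank; the first projected taxon holding more than the dynamic
#' majority [majority_threshold()] of the total volume is returned with its
#' rank. If no rank below the superkingdom yields a majority, the candidate
#' taxon with maximal volume (strictly below the viral superkingdom) is
#' returned. Ties break to the numerically smaller taxid.
#'
#' @param candidates Integer taxids from [candidate_set()].
#' @param volumes Named numeric vector of pass-2 volumes (by taxid).
#' @param tree A `taxonomy`.
#' @param params [classifier_params()].
#' @return List: `taxid`, `rank`, `majority` (threshold used), `V`.
#' @export
lca_classify <- function(candidates, volumes, tree,
                         params = classifier_params()) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  v <- volumes[as.character(candidates)]
  v[is.na(v)] <- 0
  V <- sum(v)
  m <- majority_threshold(V, params)
  walk_ranks <- setdiff(rev(params$ranks), "superkingdom")
  for (rk in walk_ranks) {
    anc <- vapply(candidates, function(t) ancestor_at_rank(tree, t, rk),
                  NA_integer_)
    ok <- !is.na(anc)
    if (!any(ok)) next
    proj <- tapply(v[ok], anc[ok], sum)
    if (V > 0) {
      share <- proj / V
      hit <- which(share > m)
      if (length(hit) > 0) {
        winners <- as.integer(names(proj)[hit])
        return(list(taxid = min(winners),
                    rank = rk, majority = m, V = V))
      }
    }
  }
  ord <- order(-v, candidates)
  best <- candidates[ord[1]]
  if (best == params$viral_taxid) {
    # never report the superkingdom itself; pick the deepest dominant child
    best <- candidates[ord[min(2L, length(candidates))]]
  }
  list(taxid = best, rank = unname(tree$rank[as.character(best)]),
       majority = m, V = V)
}

#' Classify one contig
#'
#' The full per-contig pipeline: pass-1 profiling over all (nucleotide and
#' translated) alignments of the contig against the comprehensive database;
#' the viral-superkingdom filter; the low-information filter (best pass-1
#' score below `min_contig_bits`); dynamic-radius candidate selection
#' restricted to viral taxa; pass-2 volumes; and the volume-weighted
#' rank-wise LCA. Pass-1 scores are only a barrier to entry — the LCA
#' weighs pass-2 volumes.
#'
#' @param contig One-row contig tibble (or list with `id`, `seq`).
#' @param records All alignment records with this contig as query.
#' @param tree A `taxonomy`.
#' @param params [classifier_params()].
#' @return One-row classification tibble: `contig_id`, `length`, `taxid`,
#'   `name`, `rank`, `pass1_best`, `total_volume`, `verdict`, `reason`.
#' @export
classify_contig <- function(contig, records, tree,
                            params = classifier_params()) {
  L <- nchar(contig$seq)
  row <- function(taxid, name, rank, pass1_best, total_volume, verdict,
                  reason) {
    tibble::tibble(contig_id = contig$id, length = L, taxid = taxid,
                   name = name, rank = rank, pass1_best = pass1_best,
                   total_volume = total_volume, verdict = verdict,
                   reason = reason)
  }
  if (nrow(records) == 0) {
    return(row(NA_integer_, NA_character_, NA_character_, 0, 0,
               "filtered_lowinfo", "no alignments"))
  }
  profile <- pass1(records, L, contig_id = contig$id)
  vf <- viral_filter(profile, tree, params)
  pass1_best <- max(profile$pass1_score)
  if (!vf$pass) {
    return(row(vf$top_taxid, NA_character_, NA_character_, pass1_best, 0,
               "filtered_nonviral", vf$reason))
  }
  if (pass1_best < params$min_contig_bits) {
    return(row(vf$top_taxid, NA_character_, NA_character_, pass1_best, 0,
               "filtered_lowinfo",
               sprintf("best pass-1 score %.1f bits < %g",
                       pass1_best, params$min_contig_bits)))
  }
  cand <- candidate_set(profile, params)
  cand <- cand[vapply(cand, function(t)
    is_descendant(tree, t, params$viral_taxid), TRUE)]
  vol <- pass2(records, profile, params)
  res <- lca_classify(cand, vol$volume, tree, params)
  row(res$taxid, unname(tree$name[as.character(res$taxid)]), res$rank,
      pass1_best, res$V, "classified",
      sprintf("LCA over %d candidate(s), majority %.3f", length(cand),
              res$majority))
}

#' Classify a set of contigs
#'
#' Applies [classify_contig()] to every contig and wraps the per-contig
#' rows in a `viro_classification` object with [generics::tidy()] /
#' [generics::glance()] methods.
#'
#' @param contigs Contig tibble (`id`, `seq`).
#' @param records Alignment tibble over all contigs (query = contig id).
#' @param tree A `taxonomy`.
#' @param params [classifier_params()].
#' @return A `viro_classification` object.
#' @export
classify_contigs <- function(contigs, records, tree,
                             params = classifier_params()) {
  empty <- tibble::tibble(
    contig_id = character(), length = integer(), taxid = integer(),
    name = character(), rank = character(), pass1_best = numeric(),
    total_volume = numeric(), verdict = character(), reason = character()
  )
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    classify_contig(contigs[i, ],
                    records[records$query_id == contigs$id[i], , drop = FALSE],
                    tree, params)
  })
  structure(
    list(classifications = dplyr::bind_rows(c(list(empty), rows)),
         params = params),
    class = "viro_classification"
  )
}

#' @export
print.viro_classification <- function(x, ...) {
  cl <- x$classifications
  cat("<viro_classification> ", nrow(cl), " contigs: ",
      sum(cl$verdict == "classified"), " classified, ",
      sum(cl$verdict == "filtered_nonviral"), " non-viral, ",
      sum(cl$verdict == "filtered_lowinfo"), " low-information\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-contig classification rows
#' @param x A `viro_classification`.
#' @param ... Unused.
#' @return The per-contig classification tibble.
#' @method tidy viro_classification
#' @export
tidy.viro_classification <- function(x, ...) x$classifications

#' One-row classification summary
#' @param x A `viro_classification`.
#' @param ... Unused.
#' @return One-row tibble: contig and verdict counts, total bits, number of
#'   distinct taxa among classified contigs.
#' @method glance viro_classification
#' @export
glance.viro_classification <- function(x, ...) {
  cl <- x$classifications
  tibble::tibble(
    n_contigs = nrow(cl),
    n_classified = sum(cl$verdict == "classified"),
    n_nonviral = sum(cl$verdict == "filtered_nonviral"),
    n_lowinfo = sum(cl$verdict == "filtered_lowinfo"),
    total_bits = sum(cl$pass1_best),
    n_taxa = dplyr::n_distinct(cl$taxid[cl$verdict == "classified"])
  )
}

#' Aggregate per-taxon report
#'
#' Groups classified contigs by assigned taxid, sums pass-1 bits and reads,
#' and suppresses taxa with aggregate alignment information below
#' `min_taxon_bits`. Contigs of at least `unclassified_min_len` bases that
#' were filtered (non-viral or low-information) are listed in a separate
#' unclassified section rather than silently dropped.
#'
#' @param classification A `viro_classification` (or its tidy tibble).
#' @param abundances Optional [abundance()] tibble (`contig_id`, `reads`).
#' @param params [classifier_params()] (defaults to the object's own).
#' @return List of class `viro_report`: `report` (tibble: taxid, name,
#'   rank, n_contigs, total_bits, reads, longest_contig), `unclassified`
#'   (tibble: contig_id, length, verdict, reason, reads), `suppressed`
#'   (taxa below the aggregate-bits threshold, with their numbers).
#' @export
aggregate_report <- function(classification, abundances = NULL,
                             params = NULL) {
  if (inherits(classification, "viro_classification")) {
    if (is.null(params)) params <- classification$params
    cl <- classification$classifications
  } else {
    cl <- classification
    if (is.null(params)) params <- classifier_params()
  }
  reads_of <- function(ids) {
    if (is.null(abundances)) return(rep(NA_integer_, length(ids)))
    out <- abundances$reads[match(ids, abundances$contig_id)]
    out[is.na(out)] <- 0L
    out
  }
  cl$reads <- reads_of(cl$contig_id)
  classified <- cl[cl$verdict == "classified", , drop = FALSE]
  if (nrow(classified) == 0) {
    by_tax <- tibble::tibble(taxid = integer(), name = character(),
                             rank = character(), n_contigs = integer(),
                             total_bits = numeric(), reads = integer(),
                             longest_contig = integer())
  } else by_tax <- classified |>
    dplyr::group_by(.data$taxid, .data$name, .data$rank) |>
    dplyr::summarise(n_contigs = dplyr::n(),
                     total_bits = sum(.data$pass1_best),
                     reads = sum(.data$reads),
                     longest_contig = max(.data$length),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_bits))
  keep <- by_tax$total_bits >= params$min_taxon_bits
  unclassified <- cl[cl$verdict != "classified" &
                       cl$length >= params$unclassified_min_len,
                     c("contig_id", "length", "verdict", "reason", "reads")]
  structure(
    list(report = by_tax[keep, , drop = FALSE],
         suppressed = by_tax[!keep, , drop = FALSE],
         unclassified = unclassified,
         params = params),
    class = "viro_report"
  )
}

#' @export
print.viro_report <- function(x, ...) {
  cat("<viro_report> ", nrow(x$report), " taxa reported (",
      nrow(x$suppressed), " suppressed below ", x$params$min_taxon_bits,
      " bits), ", nrow(x$unclassified), " unclassifiable contigs >= ",
      x$params$unclassified_min_len, " bp\n", sep = "")
  if (nrow(x$report) > 0) print(x$report)
  invisible(x)
}

#' Bar chart of reported taxa by aggregate alignment information
#'
#' @param object A `viro_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot viro_report
#' @export
autoplot.viro_report <- function(object, ...) {
  df <- object$report
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$name, .data$total_bits),
    y = .data$total_bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "aggregate alignment information (bits)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
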