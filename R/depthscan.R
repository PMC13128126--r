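#' Depth-classification thresholds
#'
#' Copy-number rules used to label windows: hemizygous coverage is
#' `target_half +- tol`, diploid coverage `target_full +- tol`, and a region
#' absent from a sample shows depth `< absent_max`. Comparisons are closed
#' intervals.
#'
#' @param target_half expected normalized depth of a hemizygous region (0.5).
#' @param target_full expected normalized depth of a diploid region (1).
#' @param tol half-width of both acceptance bands (0.15).
#' @param absent_max upper bound for "absent" coverage (0.15).
#' @return list of class `depth_thresholds`.
#' @export
depth_thresholds <- function(target_half = 0.5, target_full = 1.0,
                             tol = 0.15, absent_max = 0.15) {
  if (tol <= 0 || tol >= target_half)
    stopf("'tol' must satisfy 0 < tol < target_half")
  structure(list(target_half = target_half, target_full = target_full,
                 tol = tol, absent_max = absent_max),
            class = "depth_thresholds")
}

#' Normalize a per-base depth track by its genome-wide mean
#'
#' Every value is divided by the grand mean depth over all chromosome-assigned
#' positions of the sample, so the normalized track has mean exactly 1 and
#' region calls are invariant to overall sequencing effort.
#'
#' @param track named list of per-chromosome depth vectors.
#' @return named list of normalized numeric vectors, with the grand mean kept
#'   as attribute `grand_mean`.
#' @export
normalize_depth <- function(track) {
  tot <- sum(vapply(track, function(v) sum(as.numeric(v)), numeric(1)))
  n <- sum(vapply(track, length, numeric(1)))
  if (n == 0 || tot == 0) stopf("zero mean depth: cannot normalize an all-zero track")
  gm <- tot / n
  out <- lapply(track, function(v) as.numeric(v) / gm)
  attr(out, "grand_mean") <- gm
  out
}

#' Sliding-window means of a per-base track
#'
#' Windows start at 1, 1+step, ... on every chromosome; the terminal window
#' is kept (clipped at the sequence end) and flagged `partial`. Positions
#' absent from the track are depth 0 by construction of the dense vectors.
#'
#' @param track named list of per-chromosome numeric vectors (raw or
#'   normalized depth).
#' @param window_bp window size in bp.
#' @param step_bp step size in bp (`window_bp >= step_bp >= 1`).
#' @return data.table: `seq`, `start`, `end`, `mean`, `partial`.
#' @export
window_means <- function(track, window_bp, step_bp) {
  if (step_bp < 1 || window_bp < step_bp)
    stopf("need window_bp >= step_bp >= 1")
  rbindlist(lapply(names(track), function(ch) {
    v <- track[[ch]]
    L <- length(v)
    starts <- seq(1, L, by = step_bp)
    ends <- pmin(starts + window_bp - 1, L)
    cs <- c(0, cumsum(as.numeric(v)))
    data.table(seq = ch, start = starts, end = ends,
               mean = (cs[ends + 1] - cs[starts]) / (ends - starts + 1),
               partial = ends - starts + 1 < window_bp)
  }))
}

#' Label aligned male/female depth windows by copy-number signature
#'
#' * `X_like`: male hemizygous (`|male - 0.5| <= tol`) and female diploid —
#'   the X-specific signature on the shared haplotype;
#' * `Y_like`: male hemizygous and female absent (`female < absent_max`) —
#'   the Y-specific signature on the sex-limited haplotype;
#' * `balanced`: both sexes diploid; anything else is `other`.
#'
#' @param male,female window tables from [window_means()] over identical
#'   intervals.
#' @param th a [depth_thresholds()] object.
#' @return data.table with both means and a `label` column.
#' @export
classify_windows <- function(male, female, th = depth_thresholds()) {
  m <- as.data.table(male); f <- as.data.table(female)
  if (nrow(m) != nrow(f) || !all(m$seq == f$seq & m$start == f$start & m$end == f$end))
    stopf("male and female windows are not aligned on identical intervals")
  out <- data.table(seq = m$seq, start = m$start, end = m$end,
                    male = m$mean, female = f$mean,
                    partial = m$partial | f$partial)
  eps <- 1e-9  # closed-interval bounds robust to floating-point rounding
  half <- abs(out$male - th$target_half) <= th$tol + eps
  full_m <- abs(out$male - th$target_full) <= th$tol + eps
  full_f <- abs(out$female - th$target_full) <= th$tol + eps
  absent_f <- out$female < th$absent_max + eps
  out[, label := "other"]
  out[half & full_f, label := "X_like"]
  out[half & absent_f, label := "Y_like"]
  out[full_m & full_f, label := "balanced"]
  out[]
}

# threshold-crossing fraction: smallest fraction of a window that must lie
# inside the hemizygous/absent region before the window passes the label's
# thresholds. The flanking (L_out) and interior (L_in) plateau levels are
# estimated from the track itself (normalization shifts them slightly away
# from the nominal 1 / 0.5 / 0 because the hemizygous region contributes to
# the sample's grand mean), so the step-edge inversion stays unbiased. Only
# constraints that actually bind (interior passes, flank fails) contribute.
refine_crossing_fraction <- function(kind, th, m_out, m_in, f_out, f_in) {
  fr <- function(L_out, L_in, cut) {
    if (is.na(L_out) || is.na(L_in) || L_out == L_in) return(NA_real_)
    (L_out - cut) / (L_out - L_in)
  }
  f_m <- fr(m_out, m_in, th$target_half + th$tol)
  f_f <- if (kind == "X_specific") {
    # female stays diploid across an X-specific edge: non-binding
    NA_real_
  } else fr(f_out, f_in, th$absent_max)
  vals <- c(f_m, f_f)
  vals <- vals[is.finite(vals)]
  f0 <- if (length(vals)) max(vals) else 1 - th$tol / th$target_half
  min(1, max(0.5, f0))
}

#' Call sex-specific regions from labeled windows, with boundary refinement
#'
#' Within the search interval, runs of windows carrying the matching label
#' (`X_like` for `X_specific`, `Y_like` for `Y_specific`) separated by at most
#' `max_gap_bp` are merged into candidate regions. Each boundary is then
#' re-estimated at higher resolution: refine-size windows are slid at the
#' refine step across the candidate region, the first and last windows
#' passing the same depth thresholds are located, and the known response of a
#' windowed mean to a copy-number step edge is inverted (a window first passes
#' once a threshold-determined fraction of it lies inside the region), giving
#' an edge estimate that is exact in the noiseless limit rather than biased
#' outward by a fixed fraction of the window size.
#'
#' @param windows labeled window table from [classify_windows()].
#' @param kind `"X_specific"` or `"Y_specific"`.
#' @param search_seq chromosome to search.
#' @param search_interval length-2 vector, 1-based inclusive search bounds.
#' @param male_norm,female_norm normalized per-base tracks
#'   ([normalize_depth()] output) retained for refinement.
#' @param th the [depth_thresholds()] used for labeling.
#' @param refine_window_bp,refine_step_bp high-resolution window/step
#'   (defaults 20 kb / 1 kb).
#' @param max_gap_bp largest gap merged into one region (default 150 kb, one
#'   coarse window).
#' @return data.table: `seq`, `kind`, `start`, `end`, `n_windows`, `refined`;
#'   zero rows when nothing matches.
#' @export
call_regions <- function(windows, kind = c("X_specific", "Y_specific"),
                         search_seq, search_interval,
                         male_norm, female_norm,
                         th = depth_thresholds(),
                         refine_window_bp = 20000, refine_step_bp = 1000,
                         max_gap_bp = 150000) {
  kind <- match.arg(kind)
  want <- if (kind == "X_specific") "X_like" else "Y_like"
  w <- as.data.table(windows)[seq == search_seq & label == want &
                              end >= search_interval[1] & start <= search_interval[2]]
  empty <- data.table(seq = character(), kind = character(), start = numeric(),
                      end = numeric(), n_windows = integer(), refined = logical())
  if (nrow(w) == 0L) return(empty)
  setorder(w, start)
  grp <- cumsum(c(1, (w$start[-1] - w$end[-nrow(w)] - 1) > max_gap_bp))
  coarse <- w[, .(start = min(start), end = max(end), n_windows = .N), by = .(grp)]

  mvec <- male_norm[[search_seq]]; fvec <- female_norm[[search_seq]]
  msum <- cumsum(c(0, mvec)); fsum <- cumsum(c(0, fvec))
  W <- refine_window_bp
  res <- lapply(seq_len(nrow(coarse)), function(i) {
    pad <- 3 * W  # flank windows used to estimate the outside plateau level
    cs <- max(1, coarse$start[i] - pad)
    ce <- min(length(mvec), coarse$end[i] + pad)
    starts <- seq(cs, max(cs, ce - W + 1), by = refine_step_bp)
    ends <- pmin(starts + W - 1, length(mvec))
    mmean <- (msum[ends + 1] - msum[starts]) / (ends - starts + 1)
    fmean <- (fsum[ends + 1] - fsum[starts]) / (ends - starts + 1)
    eps <- 1e-9
    half <- abs(mmean - th$target_half) <= th$tol + eps
    pass <- if (kind == "X_specific")
              half & abs(fmean - th$target_full) <= th$tol + eps
            else half & fmean < th$absent_max + eps
    if (any(pass)) {
      s_first <- starts[which(pass)[1]]
      s_last <- starts[tail(which(pass), 1L)]
      interior <- starts >= s_first + W & ends <= s_last  # fully inside the run
      flank <- ends < s_first - W | starts > s_last + 2 * W
      f0 <- refine_crossing_fraction(
        kind, th,
        m_out = stats::median(mmean[flank]), m_in = stats::median(mmean[interior]),
        f_out = stats::median(fmean[flank]), f_in = stats::median(fmean[interior]))
      start <- s_first + round((1 - f0) * W)
      end <- s_last + round(f0 * W) - 1
      refined <- TRUE
    } else {
      start <- coarse$start[i]; end <- coarse$end[i]; refined <- FALSE
    }
    data.table(seq = search_seq, kind = kind,
               start = max(start, search_interval[1]),
               end = min(end, search_interval[2]),
               n_windows = coarse$n_windows[i], refined = refined)
  })
  rbindlist(res)[start <= end]
}

#' Span and gene content of a sex-specific region
#'
#' @param region one-row region (list or data.frame with `seq`, `start`,
#'   `end`).
#' @param genes gene models as a `GRanges` (e.g. from
#'   [truth_genes_granges()] or `rtracklayer::import` of a GFF3).
#' @param min_overlap_frac fraction of a gene's length that must overlap the
#'   region for the gene to count as inside (default 0.5).
#' @return list with `span_bp`, `span_mb` (rounded to one decimal), `genes`
#'   (ids when available) and `n_genes`.
#' @export
annotate_regions <- function(region, genes = NULL, min_overlap_frac = 0.5) {
  span_bp <- region$end - region$start + 1
  out <- list(span_bp = span_bp, span_mb = round(span_bp / 1e6, 1),
              genes = character(0), n_genes = 0L)
  if (!is.null(genes)) {
    reg <- GenomicRanges::GRanges(region$seq,
                                  IRanges::IRanges(region$start, region$end))
    hit <- GenomicRanges::findOverlaps(genes, reg)
    ov <- GenomicRanges::pintersect(genes[S4Vectors::queryHits(hit)],
                                    reg[S4Vectors::subjectHits(hit)])
    frac <- BiocGenerics::width(ov) / BiocGenerics::width(genes[S4Vectors::queryHits(hit)])
    inside <- S4Vectors::queryHits(hit)[frac >= min_overlap_frac]
    ids <- if (!is.null(names(genes))) names(genes)[inside]
           else if (!is.null(genes$ID)) genes$ID[inside]
           else as.character(inside)
    out$genes <- unique(ids)
    out$n_genes <- length(out$genes)
  }
  out
}

#' Percent feature coverage in sliding windows
#'
#' For each window, the percentage of non-N base pairs covered by the merged
#' feature intervals (gene or repeat density tracks). Windows consisting
#' entirely of N return NA.
#'
#' @param features `GRanges` (or `IRanges`) of features on `search_seq`.
#' @param search_seq chromosome name.
#' @param seq_length chromosome length (bp).
#' @param n_mask optional `GRanges`/`IRanges` of N runs.
#' @param window_bp,step_bp window geometry (defaults 500 kb / 100 kb).
#' @return data.table: `seq`, `start`, `end`, `density_pct`.
#' @export
feature_density <- function(features, search_seq, seq_length, n_mask = NULL,
                            window_bp = 500000, step_bp = 100000) {
  to_mask <- function(x) {
    if (is.null(x)) return(logical(seq_length))
    if (methods::is(x, "GRanges"))
      x <- IRanges::ranges(x[as.vector(GenomeInfoDb::seqnames(x)) == search_seq])
    x <- IRanges::restrict(IRanges::reduce(x), start = 1, end = seq_length)
    v <- logical(seq_length)
    if (length(x)) for (i in seq_along(x))
      v[IRanges::start(x)[i]:IRanges::end(x)[i]] <- TRUE
    v
  }
  fv <- to_mask(features)
  nv <- to_mask(n_mask)
  starts <- seq(1, seq_length, by = step_bp)
  ends <- pmin(starts + window_bp - 1, seq_length)
  csf <- c(0, cumsum(fv & !nv))
  csn <- c(0, cumsum(!nv))
  denom <- csn[ends + 1] - csn[starts]
  dens <- ifelse(denom > 0, 100 * (csf[ends + 1] - csf[starts]) / denom, NA_real_)
  data.table(seq = search_seq, start = starts, end = ends, density_pct = dens)
}

#' Export regions as BED (0-based half-open) and TSV (1-based inclusive)
#' @param regions region table from [call_regions()].
#' @param bed_path,tsv_path output paths (either may be NULL).
#' @return invisibly, the written paths.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  r <- as.data.table(regions)
  paths <- character(0)
  if (!is.null(bed_path)) {
    fwrite(r[, .(seq, start = as.integer(start - 1), end = as.integer(end),
                 name = kind)],
           bed_path, sep = "\t", col.names = FALSE)
    paths <- c(paths, bed_path)
  }
  if (!is.null(tsv_path)) {
    fwrite(r, tsv_path, sep = "\t")
    paths <- c(paths, tsv_path)
  }
  invisible(paths)
}
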