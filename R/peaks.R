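# Peak lists, residue-type classification, NOE networks and titration
# tracking.
#
# All chemical shifts are ppm. Two peaks "match" when both |dH| <= tol_H
# and |dC| <= tol_C; among several candidates the nearest in the scaled
# metric sqrt(dH^2 + (dC/alpha)^2) wins, with alpha = 5 reflecting the
# typical 13C:1H shift-spread ratio of methyl spectra.

.SHIFT_ALPHA <- 5

.scaled_dist <- function(dh, dc) sqrt(dh^2 + (dc / .SHIFT_ALPHA)^2)

#' Read an HMQC peak list
#'
#' Supports two dialects: a headered TSV with columns `peak_id`,
#' `delta_H`, `delta_C` and optionally `intensity`, `residue_type`,
#' `assignment`; or a Sparky `.list` export (`Assignment  w1  w2
#' [Data Height]`, with w1 the 13C and w2 the 1H dimension).
#'
#' @param path file path
#' @param format `"tsv"`, `"sparky"`, or `"auto"` (sniff the header)
#' @return data frame with columns `peak_id`, `delta_H`, `delta_C`,
#'   `intensity` (NA when absent), `residue_type`, `assignment`
#' @export
read_peaks <- function(path, format = c("auto", "tsv", "sparky")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("peak_id", first)) "tsv" else "sparky"
  }
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("peak_id", "delta_H", "delta_C") %in% names(df)))
      stop("TSV peak list needs columns peak_id, delta_H, delta_C")
    if (is.null(df$intensity)) df$intensity <- NA_real_
    if (is.null(df$residue_type)) df$residue_type <- NA_character_
    if (is.null(df$assignment)) df$assignment <- NA_character_
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !grepl("^Assignment", lines)]
    parts <- strsplit(lines, "[[:space:]]+")
    df <- data.frame(
      peak_id = vapply(parts, `[`, "", 1),
      delta_C = as.numeric(vapply(parts, `[`, "", 2)),
      delta_H = as.numeric(vapply(parts, `[`, "", 3)),
      intensity = vapply(parts, function(p)
        if (length(p) >= 4) as.numeric(p[4]) else NA_real_, 0),
      residue_type = NA_character_, assignment = NA_character_,
      stringsAsFactors = FALSE)
  }
  .check_peaks(df)
  df[, c("peak_id", "delta_H", "delta_C", "intensity",
         "residue_type", "assignment")]
}

#' Write an HMQC peak list as TSV
#' @param peaks peak data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_peaks <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_peaks <- function(peaks) {
  stopifnot(all(c("peak_id", "delta_H", "delta_C") %in% names(peaks)))
  if (anyDuplicated(peaks$peak_id))
    stop("duplicate peak_id: ",
         peaks$peak_id[duplicated(peaks$peak_id)][1])
  if (any(!is.finite(peaks$delta_H)) || any(!is.finite(peaks$delta_C)))
    stop("non-finite chemical shift in peak list")
  invisible(peaks)
}

# index of the peak in `peaks` matching (h, c), or NA; ties/ambiguity
# (>= 2 candidates) return the attr "n_candidates" for the caller
.match_peak <- function(h, c, peaks, tol_H, tol_C) {
  cand <- which(abs(peaks$delta_H - h) <= tol_H &
                  abs(peaks$delta_C - c) <= tol_C)
  structure(if (length(cand) == 1) cand else NA_integer_,
            candidates = cand)
}

#' Classify residue types by comparing selectively labeled samples
#'
#' Each peak of the fully labeled reference spectrum is typed by the
#' selectively labeled sample(s) it matches: a match in the Ala-only list
#' types it `Ala`, and so on. Leu/Val discrimination follows leucine
#' selective unlabeling: a reference peak matching the Leu+Val (`"LV"`)
#' list *and* the Val-only (`"V"`) list is `Val`; matching the `"LV"` list
#' only is `Leu`. Reference peaks matching selective peaks of conflicting
#' types are flagged `ambiguous` and left untyped.
#'
#' @param reference peak list of the fully labeled sample
#' @param selective named list of peak lists; names from
#'   `"M"`, `"I"`, `"A"`, `"T"`, `"LV"`, `"V"`
#' @param tol_H,tol_C match tolerances (ppm)
#' @return the reference list with `residue_type` filled in and a logical
#'   `ambiguous` column; attribute `"report"` lists per-peak evidence
#' @export
classify_residue_types <- function(reference, selective,
                                   tol_H = 0.02, tol_C = 0.2) {
  stopifnot(tol_H > 0, tol_C > 0)
  .check_peaks(reference)
  known <- c(M = "Met", I = "Ile", A = "Ala", T = "Thr")
  bad <- setdiff(names(selective), c(names(known), "LV", "V"))
  if (length(bad))
    stop("unknown selective sample label(s): ", paste(bad, collapse = ", "))

  n <- nrow(reference)
  hits <- matrix(FALSE, n, length(selective),
                 dimnames = list(NULL, names(selective)))
  for (lab in names(selective)) {
    sel <- selective[[lab]]
    .check_peaks(sel)
    for (i in seq_len(n)) {
      m <- .match_peak(reference$delta_H[i], reference$delta_C[i],
                       sel, tol_H, tol_C)
      hits[i, lab] <- length(attr(m, "candidates")) >= 1
    }
  }

  type <- rep(NA_character_, n); ambiguous <- rep(FALSE, n)
  for (i in seq_len(n)) {
    votes <- character()
    for (lab in intersect(names(known), colnames(hits)))
      if (hits[i, lab]) votes <- c(votes, known[[lab]])
    if ("LV" %in% colnames(hits) && hits[i, "LV"]) {
      votes <- c(votes,
                 if ("V" %in% colnames(hits) && hits[i, "V"]) "Val"
                 else "Leu")
    } else if ("V" %in% colnames(hits) && hits[i, "V"]) {
      votes <- c(votes, "Val")
    }
    votes <- unique(votes)
    if (length(votes) == 1) type[i] <- votes
    else if (length(votes) > 1) ambiguous[i] <- TRUE
  }
  out <- reference
  out$residue_type <- type
  out$ambiguous <- ambiguous
  attr(out, "report") <- data.frame(peak_id = reference$peak_id,
                                    hits, stringsAsFactors = FALSE)
  out
}

#' Build an NOE network from 4D cross-peaks
#'
#' Matches each 4D HMQC-NOESY-HMQC cross-peak to HMQC peaks: the
#' (f3_C, f4_H) pair locates the source node and (f1_C, f2_H) the
#' destination. An edge is created when both ends match uniquely; the
#' `mutual` flag marks edges also observed in the reversed direction.
#' Diagonal cross-peaks (source = destination) are discarded as
#' auto-peaks. Cross-peaks with an ambiguous end (>= 2 HMQC candidates)
#' or an unmatched end go to the `ambiguous` / `unmatched` reports with
#' their candidate sets.
#'
#' @param hmqc HMQC peak list
#' @param noes data frame with columns `f1_C`, `f2_H`, `f3_C`, `f4_H` and
#'   optionally `intensity`
#' @param tol_H,tol_C match tolerances (ppm)
#' @return an `noe_network`: list with `nodes` (peak ids), `edges` (data
#'   frame `from`, `to`, `mutual`, `n_cross`, `weight`), `ambiguous`,
#'   `unmatched`. One-sided edges carry weight 1/2, mutual edges weight 1.
#' @export
build_noe_network <- function(hmqc, noes, tol_H = 0.02, tol_C = 0.2) {
  stopifnot(tol_H > 0, tol_C > 0)
  .check_peaks(hmqc)
  need <- c("f1_C", "f2_H", "f3_C", "f4_H")
  stopifnot(all(need %in% names(noes)))

  n <- nrow(noes)
  src <- dst <- rep(NA_integer_, n)
  amb <- list(); unm <- list()
  for (i in seq_len(n)) {
    ms <- .match_peak(noes$f4_H[i], noes$f3_C[i], hmqc, tol_H, tol_C)
    md <- .match_peak(noes$f2_H[i], noes$f1_C[i], hmqc, tol_H, tol_C)
    cs <- attr(ms, "candidates"); cd <- attr(md, "candidates")
    if (length(cs) >= 2 || length(cd) >= 2) {
      amb[[length(amb) + 1]] <- data.frame(
        cross = i,
        source_candidates = paste(hmqc$peak_id[cs], collapse = ","),
        dest_candidates = paste(hmqc$peak_id[cd], collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    if (length(cs) == 0 || length(cd) == 0) {
      unm[[length(unm) + 1]] <- data.frame(
        cross = i, end = if (length(cs) == 0) "source" else "destination",
        stringsAsFactors = FALSE)
      next
    }
    src[i] <- ms; dst[i] <- md
  }

  ok <- !is.na(src) & !is.na(dst) & src != dst
  a <- pmin(src[ok], dst[ok]); b <- pmax(src[ok], dst[ok])
  fwd <- src[ok] < dst[ok]   # direction relative to the sorted pair
  pair <- paste(a, b)
  upairs <- sort(unique(pair))
  edges <- data.frame(from = character(), to = character(),
                      mutual = logical(), n_cross = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(upairs)) {
    ai <- as.integer(sub(" .*", "", upairs))
    bi <- as.integer(sub(".* ", "", upairs))
    n_cross <- as.integer(table(pair)[upairs])
    mutual <- vapply(upairs, function(p) {
      dirs <- fwd[pair == p]
      any(dirs) && any(!dirs)
    }, TRUE)
    edges <- data.frame(from = hmqc$peak_id[ai], to = hmqc$peak_id[bi],
                        mutual = unname(mutual), n_cross = n_cross,
                        weight = ifelse(mutual, 1, 0.5),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  out <- list(nodes = hmqc$peak_id, edges = edges,
              ambiguous = if (length(amb)) do.call(rbind, amb) else NULL,
              unmatched = if (length(unm)) do.call(rbind, unm) else NULL)
  class(out) <- "noe_network"
  out
}

#' @export
print.noe_network <- function(x, ...) {
  cat("NOE network:", length(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$mutual), "mutual ),",
      NROW(x$ambiguous), "ambiguous /", NROW(x$unmatched),
      "unmatched cross-peaks\n")
  invisible(x)
}

#' Construct a titration series
#'
#' @param points list of titration points, each a list with `ligand_total`
#'   (uM), `protein_total` (uM) and `peaks` (a peak list)
#' @param frequency_mhz spectrometer 1H frequency, used for ppm -> Hz
#'   conversion of CSPs
#' @return a `titration_series`
#' @export
titration_series <- function(points, frequency_mhz = 500) {
  lt <- vapply(points, function(p) p$ligand_total, 0)
  if (is.unsorted(lt)) stop("ligand_total must be non-decreasing")
  lapply(points, function(p) .check_peaks(p$peaks))
  out <- list(points = points, frequency_mhz = frequency_mhz)
  class(out) <- "titration_series"
  out
}

#' Track peaks along a titration
#'
#' Greedy nearest-neighbour linking of peaks between consecutive titration
#' points in the scaled shift metric. Links longer than `max_step` are
#' rejected; when two peaks claim the same successor the closer one wins
#' and the loser's trajectory is broken and flagged. The endpoint map
#' gives the first-point -> last-point peak correspondence used to
#' transfer assignments between protein states in fast exchange.
#'
#' @param series a `titration_series`
#' @param max_step maximum scaled shift step between consecutive points
#'   (ppm)
#' @return list with `trajectories` (matrix of peak ids, one row per
#'   first-point peak, NA after a break), `endpoint_map` (named character
#'   vector first-point peak -> last-point peak), `flagged` (peak ids with
#'   broken trajectories)
#' @export
track_titration <- function(series, max_step = 0.05) {
  pts <- series$points
  if (length(pts) < 2) stop("need at least two titration points")
  p0 <- pts[[1]]$peaks
  traj <- matrix(NA_character_, nrow(p0), length(pts),
                 dimnames = list(p0$peak_id, NULL))
  traj[, 1] <- p0$peak_id
  cur_h <- p0$delta_H; cur_c <- p0$delta_C
  alive <- rep(TRUE, nrow(p0))
  flagged <- character()

  for (k in 2:length(pts)) {
    pk <- pts[[k]]$peaks
    cand <- data.frame(i = integer(), j = integer(), d = numeric())
    for (i in which(alive)) {
      d <- .scaled_dist(pk$delta_H - cur_h[i], pk$delta_C - cur_c[i])
      j <- which.min(d)
      if (length(j) && d[j] <= max_step)
        cand <- rbind(cand, data.frame(i = i, j = j, d = d[j]))
    }
    taken <- rep(FALSE, nrow(pk)); linked <- rep(FALSE, nrow(p0))
    if (nrow(cand)) {
      cand <- cand[order(cand$d), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (linked[i] || taken[j]) next   # closer claimant already won
        traj[i, k] <- pk$peak_id[j]
        cur_h[i] <- pk$delta_H[j]; cur_c[i] <- pk$delta_C[j]
        linked[i] <- TRUE; taken[j] <- TRUE
      }
    }
    broke <- alive & !linked
    flagged <- union(flagged, p0$peak_id[broke])
    alive <- alive & linked
  }

  full <- !is.na(traj[, length(pts)])
  endpoint_map <- setNames(traj[full, length(pts)], p0$peak_id[full])
  list(trajectories = traj, endpoint_map = endpoint_map,
       flagged = flagged)
}
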