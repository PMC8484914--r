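cnv_event <- function(chrom, start_bp, end_bp, whole_chromosome, kind, cn, f,
                      R_event, Z_event, evidence, f_hat = f) {
  data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
             whole_chromosome = whole_chromosome, kind = kind,
             cn = as.integer(cn), f = f, f_hat = f_hat,
             size_bp = end_bp - start_bp,
             R_event = R_event, Z_event = Z_event, evidence = evidence)
}

empty_events <- function() {
  cnv_event(character(), numeric(), numeric(), logical(), character(),
            integer(), numeric(), numeric(), numeric(), character())
}

#' Call segmental CNVs from CBS segments and the HMM path
#'
#' A segment becomes an event iff `|mean_R| > R0` AND `|Z_seg| > Z0`
#' (same sign) AND its span is at least `min_size` bp — the duplication /
#' deletion rule with its 0.1 Mb resolution floor. The copy-number state
#' is the HMM majority state over the segment when its sign agrees with
#' the depth deviation, otherwise the nearest integer state to
#' `2 * (1 + mean_R)`. Adjacent events with the same state separated by
#' fewer than 2 bins are merged.
#'
#' @param segments `cnv_segments` from [cbs_segment()].
#' @param hmm_path per-bin CN vector from [viterbi_decode()].
#' @param profile the `depth_profile` both derive from.
#' @param R0 copy-ratio deviation threshold (reference band half-width).
#' @param Z0 Z threshold.
#' @param min_size minimum event span in bp.
#' @return data.frame of events (possibly zero rows).
#' @export
call_segmental_cnvs <- function(segments, hmm_path, profile,
                                R0 = 0.2, Z0 = 3, min_size = 1e5) {
  if (R0 <= 0 || Z0 <= 0 || min_size <= 0)
    stop("thresholds must be positive")
  ev <- empty_events()
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    if (is.na(s$Z_seg)) next
    size <- s$end_bp - s$start_bp
    same_sign <- sign(s$mean_R) == sign(s$Z_seg)
    if (!(abs(s$mean_R) > R0 && abs(s$Z_seg) > Z0 && same_sign &&
          size >= min_size)) next
    bins <- which(profile$chrom == s$chrom)[(s$start_bin + 1L):s$end_bin]
    states <- hmm_path[bins]
    states <- states[!is.na(states)]
    maj <- if (length(states)) {
      tab <- table(states)
      as.integer(names(tab)[which.max(tab)])
    } else NA_integer_
    hmm_agrees <- !is.na(maj) && maj != 2L && sign(maj - 2L) == sign(s$mean_R)
    cn <- if (hmm_agrees) maj else {
      g <- round(2 * (1 + s$mean_R))
      g <- max(0L, min(4L, g))
      if (g == 2L) g <- if (s$mean_R > 0) 3L else 1L
      as.integer(g)
    }
    ev <- rbind(ev, cnv_event(s$chrom, s$start_bp, s$end_bp, FALSE,
                              if (s$mean_R > 0) "duplication" else "deletion",
                              cn, 1,
                              s$mean_R, s$Z_seg,
                              if (hmm_agrees) "both" else "cbs"))
  }
  merge_adjacent_events(ev, profile)
}

# Merge same-chromosome, same-cn events separated by < 2 bins.
merge_adjacent_events <- function(ev, profile) {
  if (nrow(ev) < 2L) return(ev)
  bin_size <- attr(profile, "bin_size")
  if (is.null(bin_size)) bin_size <- stats::median(profile$end - profile$start)
  ev <- ev[order(ev$chrom, ev$start_bp), , drop = FALSE]
  keep <- list(ev[1, ])
  for (k in 2:nrow(ev)) {
    last <- keep[[length(keep)]]
    cur <- ev[k, ]
    gap <- cur$start_bp - last$end_bp
    if (cur$chrom == last$chrom && cur$cn == last$cn &&
        gap < 2 * bin_size && !cur$whole_chromosome && !last$whole_chromosome) {
      idx <- profile$chrom == cur$chrom & profile$start >= last$start_bp &
        profile$end <= cur$end_bp
      rz <- region_Z(profile, idx)
      last$end_bp <- cur$end_bp
      last$size_bp <- last$end_bp - last$start_bp
      last$R_event <- rz$R
      last$Z_event <- rz$Z
      last$evidence <- if (last$evidence == cur$evidence) last$evidence else "both"
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1L]] <- cur
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Detect whole-chromosome aneuploidy, including mosaics
#'
#' Chromosome-level detection uses the panel Z alone (with a minimum
#' implied mosaic fraction) rather than the R band: a 10% mosaic
#' monosomy has expected R of only -0.05, well inside the +/-0.2
#' reference band, yet is reported in clinical practice — so the R gate
#' applies only to segmental events. A chromosome is called when
#' `|Z_chrom| > Z0_chrom` and the implied fraction `f_hat >= f_min`,
#' where `f_hat = 2 * R_chrom / (CN - 2)` for the nearest plausible CN
#' (3 for gains, 1 for losses, 4 considered when `R_chrom > 0.75`).
#' `f_hat` is clipped to (0, 1]; values >= 0.9 are reported non-mosaic.
#'
#' @param profile a `depth_profile` with Z filled.
#' @param Z0_chrom chromosome-level Z threshold.
#' @param f_min minimum implied mosaic fraction.
#' @param chroms chromosomes to scan (default: all in the profile).
#' @param segments optional `cnv_segments`; when given, a chromosome is
#'   only eligible if its dominant segment covers at least
#'   `min_seg_cover` of its usable bins (chromosomes carved into smaller
#'   pieces carry segmental, not whole-chromosome, signal).
#' @param min_seg_cover dominant-segment coverage threshold.
#' @return data.frame of whole-chromosome events.
#' @export
detect_aneuploidy <- function(profile, Z0_chrom = 3, f_min = 0.1,
                              chroms = unique(profile$chrom),
                              segments = NULL, min_seg_cover = 0.9) {
  ev <- empty_events()
  for (ch in chroms) {
    idx <- profile$chrom == ch
    if (!is.null(segments)) {
      segs <- segments[segments$chrom == ch, , drop = FALSE]
      if (nrow(segs) && max(segs$n_bins) / sum(segs$n_bins) < min_seg_cover)
        next
    }
    rz <- region_Z(profile, idx)
    if (!is.finite(rz$Z) || abs(rz$Z) <= Z0_chrom) next
    R <- rz$R
    cn <- if (R > 0.75) 4L else if (R > 0) 3L else 1L
    f_hat <- 2 * R / (cn - 2L)
    if (!is.finite(f_hat) || f_hat < f_min) next
    f_hat <- min(f_hat, 1)
    f_rep <- if (f_hat >= 0.9) 1 else f_hat  # reporting convention
    chrom_end <- max(profile$end[idx])
    ev <- rbind(ev, cnv_event(ch, 0, chrom_end, TRUE,
                              if (R > 0) "duplication" else "deletion",
                              cn, f_rep, R, rz$Z, "chrom_z", f_hat = f_hat))
  }
  ev
}

#' Infer sample sex from corrected sex-chromosome dosage
#'
#' Dosage is the median GC-corrected depth of the chromosome relative to
#' the autosomal median: ~1 for two copies, ~0.5 for one. XY requires
#' chrY dosage > 0.25 and chrX < 0.75; XX requires chrY < 0.05 and chrX
#' near 1; anything else (e.g. monosomy X) is `undetermined`.
#'
#' @param profile a `depth_profile` (carries corrected sample depths).
#' @return "XX", "XY" or "undetermined".
#' @export
infer_sex <- function(profile) {
  corr <- attr(profile, "corrected")
  if (is.null(corr)) stop("profile lacks corrected depths")
  auto <- is_autosome(profile$chrom)
  base <- stats::median(corr[auto])
  if (!is.finite(base) || base <= 0) return("undetermined")
  dos <- function(ch) {
    i <- profile$chrom %in% ch
    if (!any(i)) return(NA_real_)
    stats::median(corr[i]) / base
  }
  dx <- dos(c("chrX", "X"))
  dy <- dos(c("chrY", "Y"))
  if (is.na(dx) || is.na(dy)) return("undetermined")
  if (dy > 0.25 && dx < 0.75) return("XY")
  if (dy < 0.05 && dx > 0.75 && dx < 1.25) return("XX")
  "undetermined"
}

chrom_token <- function(chrom) sub("^chr", "", chrom)

is_chrx <- function(chrom) chrom %in% c("chrX", "X")

clone_string <- function(whole_events, sex_token, modal_base = 46L) {
  # whole_events: rows of non-mosaic-style events forming one clone
  modal <- modal_base
  tokens <- character()
  sex <- sex_token
  if (nrow(whole_events)) {
    ord <- order(suppressWarnings(as.numeric(chrom_token(whole_events$chrom))),
                 whole_events$chrom)
    whole_events <- whole_events[ord, , drop = FALSE]
    for (k in seq_len(nrow(whole_events))) {
      e <- whole_events[k, ]
      d <- e$cn - 2L
      modal <- modal + d
      if (is_chrx(e$chrom) && e$cn == 1L) {
        sex <- "X"  # 45,X: the missing X is written in the sex token
      } else if (d > 0) {
        tokens <- c(tokens, rep(paste0("+", chrom_token(e$chrom)), d))
      } else {
        tokens <- c(tokens, rep(paste0("-", chrom_token(e$chrom)), -d))
      }
    }
  }
  paste(c(sprintf("%d,%s", modal, sex), tokens), collapse = ",")
}

#' Format an ISCN-style karyotype string
#'
#' Non-mosaic whole-chromosome events set the modal count (46 + sum of
#' CN - 2) and gain/loss tokens ("+16", "-4", repeated per extra copy;
#' tetrasomy 7 renders as "48,XN,+7,+7"); monosomy X renders as "45,X".
#' Mosaic whole-chromosome events become clones with bracketed integer
#' percentages, ordered by descending fraction with the residual normal
#' clone last (e.g. "45,X\[15%\]/46,XN\[85%\]"). Segmental CNVs are
#' appended after the numerical karyotype in the auxiliary notation
#' `dup(chrom:start-end)` / `del(chrom:start-end)`.
#'
#' @param events event data.frame (see [call_segmental_cnvs()],
#'   [detect_aneuploidy()]).
#' @param sex_call "XX", "XY" or "undetermined".
#' @param mask_sex report the sex token as "XN" (the convention for
#'   fetal material); when `FALSE`, uses the inferred XX/XY.
#' @return the karyotype string.
#' @examples
#' tri16 <- data.frame(chrom = "chr16", start_bp = 0, end_bp = 9e7,
#'                     whole_chromosome = TRUE, kind = "duplication",
#'                     cn = 3L, f = 1, size_bp = 9e7, R_event = 0.5,
#'                     Z_event = 30, evidence = "chrom_z")
#' format_karyotype(tri16, "XX")  # "47,XN,+16"
#' @export
format_karyotype <- function(events, sex_call = "undetermined",
                             mask_sex = TRUE) {
  if (is.null(events) || !nrow(events)) events <- empty_events()
  sex_token <- if (mask_sex || sex_call == "undetermined") "XN" else sex_call

  whole <- events[events$whole_chromosome, , drop = FALSE]
  seg <- events[!events$whole_chromosome, , drop = FALSE]
  if (anyDuplicated(whole$chrom))
    stop("inconsistent event set: multiple whole-chromosome states on one chromosome")
  full <- whole[whole$f >= 1, , drop = FALSE]
  mos <- whole[whole$f < 1, , drop = FALSE]

  base <- clone_string(full, sex_token)
  if (nrow(mos)) {
    mos <- mos[order(-mos$f), , drop = FALSE]
    pct <- round(100 * mos$f)
    clones <- vapply(seq_len(nrow(mos)), function(k)
      sprintf("%s[%d%%]", clone_string(rbind(full, mos[k, ]), sex_token), pct[k]),
      character(1))
    resid <- 100L - sum(pct)
    if (resid > 0)
      clones <- c(clones, sprintf("%s[%d%%]", base, resid))
    base <- paste(clones, collapse = "/")
  }

  if (nrow(seg)) {
    seg <- seg[order(seg$chrom, seg$start_bp), , drop = FALSE]
    seg_tok <- sprintf("%s(%s:%d-%d)",
                       ifelse(seg$kind == "duplication", "dup", "del"),
                       chrom_token(seg$chrom),
                       as.integer(seg$start_bp), as.integer(seg$end_bp))
    base <- paste(c(base, seg_tok), collapse = ",")
  }
  base
}

#' Parse a karyotype string emitted by [format_karyotype()]
#'
#' Test-support inverse of the formatter: recovers whole-chromosome
#' events (with mosaic fractions), segmental events, and the sex token.
#' Only the notation the formatter emits is supported.
#'
#' @param iscn karyotype string.
#' @return list with `events` (data.frame) and `sex_token`.
#' @export
parse_karyotype <- function(iscn) {
  clones <- strsplit(iscn, "/", fixed = TRUE)[[1]]
  events <- empty_events()
  sex_token <- "XN"
  for (cl in clones) {
    frac <- 1
    m <- regmatches(cl, regexec("\\[(\\d+)%\\]$", cl))[[1]]
    if (length(m)) {
      frac <- as.numeric(m[2]) / 100
      cl <- sub("\\[\\d+%\\]$", "", cl)
    }
    segs <- regmatches(cl, gregexpr("(dup|del)\\([^)]*\\)", cl))[[1]]
    cl <- gsub(",?(dup|del)\\([^)]*\\)", "", cl)
    parts <- strsplit(cl, ",", fixed = TRUE)[[1]]
    st <- parts[2]
    toks <- parts[-(1:2)]
    if (st == "X") {
      events <- rbind(events, cnv_event("chrX", 0, NA_real_, TRUE, "deletion",
                                        1L, frac, NA_real_, NA_real_, "parsed"))
    } else {
      sex_token <- st
    }
    if (length(toks)) {
      tt <- table(toks)
      for (tk in names(tt)) {
        gain <- startsWith(tk, "+")
        chrom <- paste0("chr", substring(tk, 2))
        cn <- if (gain) 2L + as.integer(tt[[tk]]) else 2L - as.integer(tt[[tk]])
        dup <- events$whole_chromosome & events$chrom == chrom & events$f == frac
        if (!any(dup))
          events <- rbind(events, cnv_event(chrom, 0, NA_real_, TRUE,
                                            if (gain) "duplication" else "deletion",
                                            cn, frac, NA_real_, NA_real_, "parsed"))
      }
    }
    for (sg in segs) {
      g <- regmatches(sg, regexec("(dup|del)\\(([^:]+):(\\d+)-(\\d+)\\)", sg))[[1]]
      events <- rbind(events, cnv_event(paste0("chr", g[3]),
                                        as.numeric(g[4]), as.numeric(g[5]), FALSE,
                                        if (g[2] == "dup") "duplication" else "deletion",
                                        if (g[2] == "dup") 3L else 1L, 1,
                                        NA_real_, NA_real_, "parsed"))
    }
  }
  # residual normal clone contributes no events; mosaic fractions kept as parsed
  list(events = events, sex_token = sex_token)
}

#' Classify a sample's result category
#'
#' Categories follow clinical reporting for products-of-conception
#' screening: `numerical abnormality` (any non-mosaic whole-chromosome
#' event), `chimera` (only mosaic whole-chromosome events), `structural
#' abnormality` (only segmental events), else `normal`. When classes
#' mix, precedence is numerical > chimera > structural and the report is
#' flagged mixed.
#'
#' @param events event data.frame.
#' @return character class, with attribute `mixed` when applicable.
#' @export
classify_result <- function(events) {
  if (is.null(events) || !nrow(events)) return("normal")
  whole_full <- any(events$whole_chromosome & events$f >= 1)
  whole_mos <- any(events$whole_chromosome & events$f < 1)
  seg <- any(!events$whole_chromosome)
  kinds <- sum(c(whole_full, whole_mos, seg))
  cls <- if (whole_full) "numerical abnormality"
         else if (whole_mos) "chimera"
         else if (seg) "structural abnormality"
         else "normal"
  if (kinds > 1L) attr(cls, "mixed") <- TRUE
  cls
}
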