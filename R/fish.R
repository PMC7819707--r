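#' Simulate straightened dendrite smFISH intensity profiles
#'
#' Punctum positions are drawn from an inhomogeneous Poisson process along
#' the dendrite (rate in puncta/micron, constant or a function of distance
#' from the soma); the profile is a sum of Gaussian bumps (sd =
#' \code{psf_sigma_um}, the in-profile point-spread width) plus white
#' noise. A marker channel is generated the same way with a high punctum
#' rate for marker-positive dendrites and a low rate for negatives.
#'
#' @param n_profiles number of dendrites.
#' @param length_um tracked length per dendrite; a single value or one per
#'   profile.
#' @param step_um uniform sampling step of the profile.
#' @param punctum_rate puncta per micron: a scalar or a function of
#'   distance (must be non-negative everywhere).
#' @param psf_sigma_um Gaussian bump sd (> 0).
#' @param amplitude bump peak amplitude (arbitrary units).
#' @param noise_sd white-noise sd.
#' @param marker_labels logical vector of marker-positive dendrites
#'   (default: first half positive).
#' @param marker_rate_pos,marker_rate_neg marker-channel punctum rates for
#'   positive / negative dendrites.
#' @param seed integer seed.
#' @return list with \code{profiles} (long data.frame: \code{profile_id},
#'   \code{position_um}, \code{channel} in \code{c("gene", "marker")},
#'   \code{intensity}) and \code{truth} (\code{punctum_positions} per
#'   profile, \code{marker_labels}, \code{tracked_length}).
#' @export
simulateProfiles <- function(n_profiles = 100L, length_um = 60,
                             step_um = 0.1, punctum_rate = 0.1,
                             psf_sigma_um = 0.5, amplitude = 1,
                             noise_sd = 0.1, marker_labels = NULL,
                             marker_rate_pos = 0.5, marker_rate_neg = 0.02,
                             seed = 1L) {
    if (psf_sigma_um <= 0) stop("psf_sigma_um must be positive")
    ratefun <- if (is.function(punctum_rate)) punctum_rate else
        function(x) rep(punctum_rate, length(x))
    lengths <- rep_len(length_um, n_profiles)
    if (is.null(marker_labels))
        marker_labels <- seq_len(n_profiles) <= n_profiles / 2
    marker_labels <- rep_len(marker_labels, n_profiles)
    set.seed(seed)

    drawPoints <- function(len, rf) {
        grid <- seq(0, len, by = min(step_um, 0.05))
        r <- rf(grid)
        if (any(r < 0)) stop("punctum_rate must be non-negative")
        rmax <- max(r)
        if (rmax == 0) return(numeric(0))
        n <- stats::rpois(1, rmax * len)
        if (n == 0) return(numeric(0))
        xs <- stats::runif(n, 0, len)
        keep <- stats::runif(n) < rf(xs) / rmax
        sort(xs[keep])
    }
    render <- function(pos, grid) {
        y <- numeric(length(grid))
        for (p in pos)
            y <- y + amplitude * exp(-(grid - p)^2 / (2 * psf_sigma_um^2))
        if (noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, noise_sd)
        pmax(y, 0)   # intensities are non-negative (arbitrary units)
    }

    ids <- sprintf("dend%04d", seq_len(n_profiles))
    rows <- vector("list", n_profiles)
    puncta <- vector("list", n_profiles)
    for (i in seq_len(n_profiles)) {
        grid <- seq(0, lengths[i], by = step_um)
        pos <- drawPoints(lengths[i], ratefun)
        puncta[[i]] <- pos
        mrate <- if (marker_labels[i]) marker_rate_pos else marker_rate_neg
        mpos <- drawPoints(lengths[i], function(x) rep(mrate, length(x)))
        rows[[i]] <- data.frame(
            profile_id = ids[i],
            position_um = c(grid, grid),
            channel = rep(c("gene", "marker"), each = length(grid)),
            intensity = c(render(pos, grid), render(mpos, grid)))
    }
    names(puncta) <- ids
    list(profiles = do.call(rbind, rows),
         truth = list(punctum_positions = puncta,
                      marker_labels = stats::setNames(marker_labels, ids),
                      tracked_length = stats::setNames(lengths, ids)))
}

#' Read / write dendrite profiles as long TSV
#'
#' Columns: \code{profile_id}, \code{position_um}, \code{channel},
#' \code{intensity}. Positions must start at 0 (the soma end) and ascend in
#' a uniform step; irregular inputs are resampled to a uniform step by
#' linear interpolation on read.
#'
#' @param path TSV path.
#' @param profiles long data.frame of profiles.
#' @export
readProfiles <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("profile_id", "position_um", "channel", "intensity")
    if (!all(need %in% colnames(df)))
        stop("profile TSV must have columns: ", paste(need, collapse = ", "))
    out <- lapply(split(df, list(df$profile_id, df$channel), drop = TRUE),
                  function(d) {
        d <- d[order(d$position_um), ]
        steps <- diff(d$position_um)
        if (length(steps) && diff(range(steps)) > 1e-8 * max(steps)) {
            step <- stats::median(steps)
            grid <- seq(min(d$position_um), max(d$position_um), by = step)
            d2 <- d[rep(1, length(grid)), ]
            d2$position_um <- grid
            d2$intensity <- stats::approx(d$position_um, d$intensity,
                                          grid)$y
            d <- d2
        }
        d
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' @rdname readProfiles
#' @export
writeProfiles <- function(profiles, path) {
    utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# Gaussian smoothing with edge replication
.gaussSmooth <- function(y, sigma, step) {
    half <- max(1L, ceiling(3 * sigma / step))
    k <- stats::dnorm(seq(-half, half) * step, 0, sigma)
    k <- k / sum(k)
    padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
    as.numeric(stats::filter(padded, k, sides = 2))[half + seq_along(y)]
}

# prominence of each local maximum: height minus the higher of the two
# valley floors separating it from the nearest taller point on either side
.peakProminence <- function(y, peaks) {
    vapply(peaks, function(p) {
        h <- y[p]
        left <- y[seq_len(p - 1)]
        taller_l <- which(left > h)
        base_l <- min(y[(if (length(taller_l)) max(taller_l) else 1):p])
        right <- y[seq(p + 1, length(y))]
        taller_r <- which(right > h)
        hi <- if (length(taller_r)) p + min(taller_r) else length(y)
        base_r <- min(y[p:hi])
        h - max(base_l, base_r)
    }, numeric(1))
}

#' Detect signal puncta in an intensity profile
#'
#' Profiles are first denoised by a short Gaussian matched filter
#' (\code{smooth_um}; set to 0 to disable). Local maxima with prominence at
#' or above \code{min_prominence} times the channel's robust maximum (the
#' 99th percentile of the channel's intensities pooled over all dendrites,
#' so that signal-free dendrites contribute no spurious puncta) and
#' pairwise separation of at least \code{min_separation} microns are
#' reported as puncta; peak positions are refined to sub-step precision by
#' parabolic interpolation. An all-zero (or flat) channel yields an empty
#' set.
#'
#' @param profiles long profile data.frame (or the result list of
#'   \code{\link{simulateProfiles}}).
#' @param channel channel to analyze.
#' @param min_prominence prominence threshold as a fraction of the robust
#'   (99th percentile, channel-wide) maximum.
#' @param min_separation minimum punctum separation in microns.
#' @param smooth_um sd (microns) of the Gaussian denoising filter.
#' @return data.frame with columns \code{profile_id}, \code{position_um},
#'   \code{intensity}.
#' @export
detectPeaks <- function(profiles, channel = "gene", min_prominence = 0.2,
                        min_separation = 1, smooth_um = 0.3) {
    if (is.list(profiles) && !is.data.frame(profiles))
        profiles <- profiles$profiles
    df <- profiles[profiles$channel == channel, ]
    robust_max <- stats::quantile(df$intensity, 0.99, names = FALSE)
    if (robust_max <= 0)
        return(data.frame(profile_id = character(0),
                          position_um = numeric(0), intensity = numeric(0)))
    out <- lapply(split(df, df$profile_id, drop = TRUE), function(d) {
        d <- d[order(d$position_um), ]
        y <- d$intensity
        pos <- d$position_um
        n <- length(y)
        if (n < 3) return(NULL)
        step <- pos[2] - pos[1]
        if (diff(range(diff(pos))) > 1e-6 * step)
            stop("profile sampling must be uniform (see readProfiles)")
        if (smooth_um > 0) y <- .gaussSmooth(y, smooth_um, step)
        thr <- min_prominence * robust_max
        cand <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n]) + 1L
        if (!length(cand)) return(NULL)
        prom <- .peakProminence(y, cand)
        cand <- cand[prom >= thr]
        if (!length(cand)) return(NULL)
        # enforce separation greedily from the tallest peak down
        cand <- cand[order(-y[cand])]
        kept <- integer(0)
        for (p in cand)
            if (!length(kept) ||
                all(abs(pos[p] - pos[kept]) >= min_separation))
                kept <- c(kept, p)
        kept <- sort(kept)
        # parabolic sub-step interpolation around each kept maximum
        refine <- vapply(kept, function(p) {
            if (p == 1L || p == n) return(pos[p])
            denom <- y[p - 1] - 2 * y[p] + y[p + 1]
            if (denom >= 0) return(pos[p])
            pos[p] + 0.5 * step * (y[p - 1] - y[p + 1]) / denom
        }, numeric(1))
        data.frame(profile_id = d$profile_id[1], position_um = refine,
                   intensity = y[kept])
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(profile_id = character(0),
                          position_um = numeric(0), intensity = numeric(0))
    rownames(out) <- NULL
    out
}

#' Classify dendrites by marker-channel intensity
#'
#' A dendrite is marker-positive when its mean marker intensity reaches the
#' threshold; \code{"otsu"} derives the threshold from the bimodal
#' distribution of mean intensities (falling back to the midpoint, with a
#' warning, when the distribution is not separable).
#'
#' @param profiles long profile data.frame.
#' @param marker_channel channel holding the cell-type marker signal.
#' @param threshold numeric intensity or \code{"otsu"}.
#' @return list with \code{positive} (named logical per dendrite),
#'   \code{mean_intensity} and the \code{threshold} used.
#' @export
classifyMarker <- function(profiles, marker_channel = "marker",
                           threshold = "otsu") {
    if (is.list(profiles) && !is.data.frame(profiles))
        profiles <- profiles$profiles
    df <- profiles[profiles$channel == marker_channel, ]
    if (!nrow(df)) stop("marker channel not present")
    mi <- tapply(df$intensity, df$profile_id, mean)
    if (identical(threshold, "otsu")) {
        thr <- .otsu(mi)
        if (is.na(thr)) {
            warning("marker intensities not separable; using the midpoint")
            thr <- mean(range(mi))
        }
    } else thr <- threshold
    list(positive = stats::setNames(as.vector(mi) >= thr, names(mi)),
         mean_intensity = mi, threshold = thr)
}

# Otsu's threshold on a numeric vector (histogram-based between-class
# variance maximization); NA when the split is degenerate
.otsu <- function(v, n_breaks = 256L) {
    if (length(unique(v)) < 2L) return(NA_real_)
    h <- graphics::hist(v, breaks = n_breaks, plot = FALSE)
    p <- h$counts / sum(h$counts)
    mids <- h$mids
    w1 <- cumsum(p)
    m1 <- cumsum(p * mids)
    mt <- m1[length(m1)]
    between <- (mt * w1 - m1)^2 / pmax(w1 * (1 - w1), 1e-12)
    between <- between[-length(between)]
    top <- max(between)
    if (!is.finite(top) || top <= 0) return(NA_real_)
    # midpoint of the maximal plateau: the gap between modes is flat
    k <- which(between >= top * (1 - 1e-9))
    mean(mids[c(min(k), max(k) + 1L)])
}

#' Assemble a punctum raster sorted by marker status
#'
#' Orders dendrites as in the published raster figures: marker-negative
#' rows first (above the red line), marker-positive rows below, each block
#' sorted by mean marker intensity; each row carries its end-of-track
#' position. A punctum-density summary per 10-micron bin per marker group
#' is attached.
#'
#' @param profiles long profile data.frame (for track lengths and marker
#'   intensities).
#' @param puncta punctum table from \code{\link{detectPeaks}}.
#' @param marker result of \code{\link{classifyMarker}} (or a named logical
#'   vector of marker flags).
#' @param bin_um density bin width in microns.
#' @return list of class \code{"sdRaster"} with \code{rows} (ordered
#'   data.frame: \code{profile_id}, \code{marker_positive},
#'   \code{marker_intensity}, \code{tracked_length}, \code{row}),
#'   \code{puncta} (with row assignments) and \code{density}
#'   (\code{group}, \code{bin_start}, \code{bin_end}, \code{puncta},
#'   \code{track_um}, \code{density_per_um}).
#' @export
buildRaster <- function(profiles, puncta, marker, bin_um = 10) {
    if (is.list(profiles) && !is.data.frame(profiles))
        profiles <- profiles$profiles
    if (is.list(marker) && !is.null(marker$positive))
        marker_flags <- marker$positive
    else marker_flags <- marker
    ids <- unique(profiles$profile_id)
    tl <- tapply(profiles$position_um, profiles$profile_id, max)[ids]
    mi <- if (is.list(marker) && !is.null(marker$mean_intensity))
        as.vector(marker$mean_intensity[ids]) else rep(NA_real_, length(ids))
    flags <- as.logical(marker_flags[ids])
    rows <- data.frame(profile_id = ids, marker_positive = flags,
                       marker_intensity = mi,
                       tracked_length = as.vector(tl),
                       stringsAsFactors = FALSE)
    rows <- rows[order(rows$marker_positive, rows$marker_intensity,
                       rows$profile_id), ]
    rows$row <- seq_len(nrow(rows))
    puncta$row <- rows$row[match(puncta$profile_id, rows$profile_id)]

    mx <- max(rows$tracked_length)
    starts <- seq(0, mx - 1e-9, by = bin_um)
    dens <- do.call(rbind, lapply(c(FALSE, TRUE), function(grp) {
        sel <- rows$marker_positive == grp
        if (!any(sel)) return(NULL)
        pid <- rows$profile_id[sel]
        pp <- puncta[puncta$profile_id %in% pid, ]
        data.frame(group = if (grp) "marker_positive" else "marker_negative",
                   bin_start = starts, bin_end = starts + bin_um,
                   puncta = vapply(starts, function(b)
                       sum(pp$position_um >= b & pp$position_um < b + bin_um),
                       numeric(1)),
                   track_um = vapply(starts, function(b)
                       sum(pmin(pmax(rows$tracked_length[sel] - b, 0),
                                bin_um)), numeric(1)))
    }))
    dens$density_per_um <- ifelse(dens$track_um > 0,
                                  dens$puncta / dens$track_um, 0)
    structure(list(rows = rows, puncta = puncta, density = dens),
              class = "sdRaster")
}

#' Plot a punctum raster
#'
#' Draws detected puncta as vertical bars per dendrite row, the end of each
#' tracked dendrite as a grey tick, and the marker split as a red line,
#' mirroring the published raster figures.
#'
#' @param x an \code{"sdRaster"} from \code{\link{buildRaster}}.
#' @param ... passed to \code{plot}.
#' @export
plotRaster <- function(x, ...) {
    rows <- x$rows
    graphics::plot(NA, xlim = c(0, max(rows$tracked_length)),
                   ylim = c(nrow(rows) + 1, 0), xlab = "distance (µm)",
                   ylab = "dendrite", yaxs = "i", ...)
    graphics::segments(rows$tracked_length, rows$row - 0.4,
                       rows$tracked_length, rows$row + 0.4, col = "grey70")
    if (nrow(x$puncta))
        graphics::segments(x$puncta$position_um, x$puncta$row - 0.4,
                           x$puncta$position_um, x$puncta$row + 0.4)
    split <- sum(!rows$marker_positive)
    if (split > 0 && split < nrow(rows))
        graphics::abline(h = split + 0.5, col = "red")
    invisible(x)
}
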