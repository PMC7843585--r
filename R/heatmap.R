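#' Percent change between successive densities, per organ
#'
#' For an ordered sequence of profiles (strictly increasing density),
#' computes for each organ a matrix of percent changes between successive
#' densities: cell(rank, j) = 100 * (size_{j+1} - size_j) / size_j. This is
#' the matrix behind the canopy-size heatmap; note it differs from the
#' regression scale, which is change relative to the reference density
#' (see [reference_change_matrix()]).
#'
#' @param profiles List of [base_profile]s ordered by density.
#' @return Named list (per organ) of 13 x (n-1) matrices; rows are ranks,
#'   columns transitions labelled "PDa->PDb". Cells with a zero
#'   denominator are NA.
#' @export
successive_change_matrix <- function(profiles) {
  if (length(profiles) < 2) abort_domain("need at least two profiles")
  dens <- vapply(profiles, function(p) p$density, numeric(1))
  if (any(diff(dens) <= 0)) abort_domain("profiles must be ordered by strictly increasing density")
  ranks <- modeled_ranks()
  cols <- paste0("PD", dens[-length(dens)], "->PD", dens[-1])
  lapply(stats::setNames(organ_codes(), organ_codes()), function(code) {
    sizes <- vapply(profiles, profile_sizes, numeric(length(ranks)), organ = code)
    from <- sizes[, -ncol(sizes), drop = FALSE]
    to <- sizes[, -1, drop = FALSE]
    m <- 100 * (to - from) / from
    m[from == 0] <- NA_real_
    dimnames(m) <- list(rank = ranks, transition = cols)
    m
  })
}

#' Percent change relative to the reference-density profile, per organ
#'
#' The regression-scale companion of [successive_change_matrix()]: each
#' column is the percent change of an elevated-density profile relative to
#' the first (reference) profile.
#'
#' @inheritParams successive_change_matrix
#' @return Named list (per organ) of 13 x (n-1) matrices.
#' @export
reference_change_matrix <- function(profiles) {
  if (length(profiles) < 2) abort_domain("need at least two profiles")
  dens <- vapply(profiles, function(p) p$density, numeric(1))
  if (any(diff(dens) <= 0)) abort_domain("profiles must be ordered by strictly increasing density")
  ranks <- modeled_ranks()
  cols <- paste0("PD", dens[1], "->PD", dens[-1])
  lapply(stats::setNames(organ_codes(), organ_codes()), function(code) {
    sizes <- vapply(profiles, profile_sizes, numeric(length(ranks)), organ = code)
    ref <- sizes[, 1]
    m <- 100 * (sizes[, -1, drop = FALSE] - ref) / ref
    m[ref == 0, ] <- NA_real_
    dimnames(m) <- list(rank = ranks, transition = cols)
    m
  })
}

#' Render the organ-size change heatmap
#'
#' One panel per organ; a diverging red-to-green scale with fixed limits
#' (default -16 to +10 percent; values outside are clamped to the limits
#' before rendering, so the rendered scale limits equal the configured
#' ones exactly). Rank 18 (canopy top) is drawn at the top. When the
#' reference profile is supplied, its absolute sizes are printed as
#' numerals in a leading column.
#'
#' @param matrices Per-organ change matrices from
#'   [successive_change_matrix()].
#' @param path Output image path (`.png`, or `.svg` where cairo is
#'   available).
#' @param limits Color-scale limits in percent, default `c(-16, 10)`.
#' @param base Optional reference [base_profile] whose sizes label the
#'   first column.
#' @param top_rank_first Draw the highest rank at the top (default TRUE).
#' @return The ggplot object, invisibly (the file is written as a side
#'   effect).
#' @export
render_heatmap <- function(matrices, path, limits = c(-16, 10), base = NULL,
                           top_rank_first = TRUE) {
  if (!length(matrices)) abort_domain("no change matrices supplied")
  stopifnot(length(limits) == 2, limits[1] < limits[2])
  long <- do.call(rbind, lapply(names(matrices), function(code) {
    m <- matrices[[code]]
    data.frame(organ = code,
               rank = as.integer(rep(rownames(m), ncol(m))),
               transition = rep(colnames(m), each = nrow(m)),
               change = as.vector(m))
  }))
  long$change_clamped <- pmin(limits[2], pmax(limits[1], long$change))
  trans_levels <- colnames(matrices[[1]])
  long$transition <- factor(long$transition, levels = trans_levels)
  rank_levels <- if (top_rank_first) sort(unique(long$rank)) else rev(sort(unique(long$rank)))
  long$rank_f <- factor(long$rank, levels = rank_levels)
  long$organ <- factor(long$organ, levels = names(matrices))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$transition, y = .data$rank_f,
                                          fill = .data$change_clamped)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#c0392b", mid = "#fdf6e3", high = "#1e8449",
                                  midpoint = 0, limits = limits,
                                  name = "change (%)") +
    ggplot2::facet_wrap(~organ, nrow = 2) +
    ggplot2::labs(x = "density transition", y = "phytomer rank") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(base)) {
    labels <- do.call(rbind, lapply(names(matrices), function(code) {
      s <- profile_sizes(base, code)
      data.frame(organ = factor(code, levels = names(matrices)),
                 rank_f = factor(names(s), levels = rank_levels),
                 label = sprintf("%.1f", unname(s)))
    }))
    p <- p + ggplot2::geom_text(data = labels,
      ggplot2::aes(x = 0.4, y = .data$rank_f, label = .data$label),
      inherit.aes = FALSE, size = 2, hjust = 1) +
      ggplot2::coord_cartesian(xlim = c(-0.3, length(trans_levels)), clip = "off") +
      ggplot2::theme(plot.margin = ggplot2::margin(5, 5, 5, 30))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    if (isTRUE(unname(capabilities("cairo")))) {
      grDevices::svg(path, width = 8, height = 5)
      print(p); grDevices::dev.off()
    } else abort_domain("SVG output needs cairo; use a .png path")
  } else {
    grDevices::png(path, width = 1600, height = 1000, res = 200)
    print(p); grDevices::dev.off()
  }
  invisible(p)
}

#' Write change matrices as delimited text
#'
#' @param matrices Per-organ change matrices.
#' @param path Output CSV path (long form: organ, rank, transition, change).
#' @return `path`, invisibly.
#' @export
write_change_matrices <- function(matrices, path) {
  long <- do.call(rbind, lapply(names(matrices), function(code) {
    m <- matrices[[code]]
    data.frame(organ = code, rank = rep(rownames(m), ncol(m)),
               transition = rep(colnames(m), each = nrow(m)),
               change_percent = as.vector(m))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
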