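#' Region annotation of a synuclein-like chain
#'
#' Describes the visible chain: its sequence, the N-terminal / NAC /
#' C-terminal regions (1-based inclusive intervals that tile the sequence
#' without overlap), an optional hot-spot interval (must lie within the
#' N-terminal region) and the spin-label (MTSL) sites used on the partner
#' chain.
#'
#' @param sequence amino-acid string.
#' @param regions named list of `c(start, end)` intervals with names
#'   `"N"`, `"NAC"`, `"C"`.
#' @param hotspot optional `c(start, end)` inside the N-terminal region.
#' @param mtsl_sites integer vector of spin-label positions.
#' @return object of class `region_map`.
#' @export
#' @examples
#' region_map(synuclein_sequence("alpha"))
region_map <- function(sequence,
                       regions = NULL,
                       hotspot = c(38L, 45L),
                       mtsl_sites = integer()) {
  stopifnot(is.character(sequence), nchar(sequence) >= 1L)
  len <- nchar(sequence)
  if (is.null(regions)) regions <- default_regions(len)
  stopifnot(all(c("N", "NAC", "C") %in% names(regions)))
  iv <- do.call(rbind, regions[c("N", "NAC", "C")])
  if (any(iv < 1L) || any(iv > len) || any(iv[, 1L] > iv[, 2L]))
    abort2("region intervals must lie within [1, sequence length]",
           "prekd_regions")
  covered <- sort(unname(unlist(mapply(seq, iv[, 1L], iv[, 2L],
                                       SIMPLIFY = FALSE))))
  if (!identical(covered, 1:len))
    abort2("N/NAC/C regions must tile the sequence without overlap",
           "prekd_regions")
  if (!is.null(hotspot)) {
    if (hotspot[1L] < regions$N[1L] || hotspot[2L] > regions$N[2L])
      abort2("hot spot must lie within the N-terminal region", "prekd_regions")
  }
  structure(list(sequence = sequence, regions = regions, hotspot = hotspot,
                 mtsl_sites = as.integer(mtsl_sites)),
            class = "region_map")
}

# standard synuclein boundaries; alpha (140 aa): N 1-60, NAC 61-95, C 96-140;
# beta (134 aa): N 1-60, NAC 61-84, C 85-134. Other lengths: proportional.
default_regions <- function(len) {
  if (len == 140L) list(N = c(1L, 60L), NAC = c(61L, 95L), C = c(96L, 140L))
  else if (len == 134L) list(N = c(1L, 60L), NAC = c(61L, 84L), C = c(85L, 134L))
  else {
    a <- round(len * 60 / 140); b <- round(len * 95 / 140)
    list(N = c(1L, a), NAC = c(a + 1L, b), C = c(b + 1L, len))
  }
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d aa; N %d-%d, NAC %d-%d, C %d-%d; labels: %s\n",
              nchar(x$sequence),
              x$regions$N[1], x$regions$N[2], x$regions$NAC[1],
              x$regions$NAC[2], x$regions$C[1], x$regions$C[2],
              paste(x$mtsl_sites, collapse = ", ")))
  invisible(x)
}

#' Region containing a residue
#' @param rmap a [region_map()].
#' @param residue residue index or vector of indices.
#' @return character vector of region names ("N", "NAC", "C").
#' @export
region_of <- function(rmap, residue) {
  vapply(residue, function(r) {
    for (nm in c("N", "NAC", "C"))
      if (r >= rmap$regions[[nm]][1L] && r <= rmap$regions[[nm]][2L]) return(nm)
    NA_character_
  }, character(1))
}

#' Colour-scale bin of a PRE rate
#'
#' Pure rendering function: values <= 0 clamp to the bottom bin, bins are
#' linear in 2 s^-1 steps up to 12 s^-1, and values above 12 s^-1 saturate
#' the top ("red") bin, mirroring the conventional contact-map display
#' where rates above 12 Hz mark strong interactions.
#'
#' @param x numeric PRE rates.
#' @param breaks increasing bin boundaries (default `seq(0, 12, 2)`).
#' @return integer bin index in `1:(length(breaks) + 1)`; the top index is
#'   the saturated > 12 s^-1 bin.
#' @export
bin_gamma2 <- function(x, breaks = seq(0, 12, 2)) {
  findInterval(pmax(as.numeric(x), 0), breaks, left.open = TRUE) + 1L
}

#' Assemble a multi-strip contact map
#'
#' Combines the PRE profiles of several spin-label sites against the same
#' visible chain into one contact map. Strips are ordered by ascending
#' spin-label site. The stored profile values are never altered by
#' rendering; the binned matrix is a pure function of `gamma2`
#' ([bin_gamma2()]).
#'
#' @param profiles list of `pre_profile` objects (one per spin-label site)
#'   sharing the same visible species.
#' @param regions a [region_map()] for the visible chain.
#' @return object of class `contact_map` with elements `strips` (profiles
#'   keyed by site), `table` (long tibble), `binned` (site x residue bin
#'   matrix), `regions`.
#' @export
build_contact_map <- function(profiles, regions) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "pre_profile")),
            inherits(regions, "region_map"))
  meta <- lapply(profiles, attr, "sample")
  vis <- vapply(meta, function(m) as.character(m$visible_species %||% NA),
                character(1))
  if (length(unique(vis[!is.na(vis)])) > 1L)
    abort2("all strips must share the same visible species", "prekd_metadata")
  sites <- vapply(meta, function(m) as.integer(m$label_site %||% NA), integer(1))
  if (anyNA(sites))
    abort2("every profile needs a 'label_site' in its sample metadata",
           "prekd_metadata")
  ord <- order(sites)
  profiles <- profiles[ord]; sites <- sites[ord]
  names(profiles) <- sites
  len <- nchar(regions$sequence)
  tab <- dplyr::bind_rows(lapply(profiles, function(p) {
    m <- attr(p, "sample")
    tibble::tibble(spin_label_site = as.integer(m$label_site),
                   visible_species = as.character(m$visible_species %||% NA),
                   residue = p$residue, gamma2 = p$gamma2,
                   gamma2_error = p$gamma2_error, significant = p$significant)
  }))
  binned <- matrix(NA_integer_, nrow = length(sites), ncol = len,
                   dimnames = list(sites, seq_len(len)))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    binned[k, p$residue] <- bin_gamma2(p$gamma2)
  }
  structure(list(strips = profiles, sites = sites, table = tab,
                 binned = binned, regions = regions),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d strips (sites %s), %d-aa visible chain, %d significant cells\n",
              length(x$strips), paste(x$sites, collapse = ", "),
              nchar(x$regions$sequence), sum(x$table$significant)))
  invisible(x)
}

# longest run of TRUE within a logical vector
longest_run <- function(mask) {
  if (!length(mask) || !any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Per-region interaction summary and dimer topology
#'
#' For every (strip, region) pair reports the number of significant
#' residues, the mean and maximum significant \eqn{\Gamma_2}, and whether
#' the pair counts as interacting (at least `min_run` contiguous
#' significant residues in the region, a guard against single-residue
#' noise passes). Dimer topology is classified from the interacting pairs:
#' a probe in the N-terminal region contacting the N-terminal region is a
#' head-to-head configuration; an N-probe contacting the C-terminal region
#' (or a C-probe the N-terminal region) is head-to-tail.
#'
#' @param map a [contact_map()].
#' @param min_run minimum contiguous significant run for an interaction.
#' @return object of class `region_summary`: list with `table` (tibble)
#'   and `topology` (character vector; empty means no interaction).
#' @export
region_summary <- function(map, min_run = 3L) {
  stopifnot(inherits(map, "contact_map"))
  rmap <- map$regions
  rows <- list(); topo <- character(0)
  for (k in seq_along(map$strips)) {
    p <- map$strips[[k]]
    site <- map$sites[k]
    probe_region <- region_of(rmap, site)
    for (nm in c("N", "NAC", "C")) {
      iv <- rmap$regions[[nm]]
      span <- seq(iv[1L], iv[2L])
      sig_res <- p$residue[p$significant]
      in_reg <- p[p$residue %in% span & p$significant, ]
      mask <- span %in% sig_res
      interacting <- longest_run(mask) >= min_run
      rows[[length(rows) + 1L]] <- tibble::tibble(
        spin_label_site = site, probe_region = probe_region, region = nm,
        n_significant = nrow(in_reg),
        mean_gamma2 = if (nrow(in_reg)) mean(in_reg$gamma2) else NA_real_,
        max_gamma2 = if (nrow(in_reg)) max(in_reg$gamma2) else NA_real_,
        interacting = interacting)
      if (interacting) {
        if (probe_region == "N" && nm == "N") topo <- c(topo, "head-to-head")
        if ((probe_region == "N" && nm == "C") ||
            (probe_region == "C" && nm == "N")) topo <- c(topo, "head-to-tail")
      }
    }
  }
  structure(list(table = dplyr::bind_rows(rows), topology = unique(topo)),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat("<region_summary> topology:",
      if (length(x$topology)) paste(x$topology, collapse = " + ") else "none",
      "\n")
  print(x$table, n = Inf)
  invisible(x)
}

#' Plot a contact map as a binned heat map
#'
#' @param x a [contact_map()].
#' @param ... unused.
#' @return a ggplot object (strips on the y axis, residues on the x axis,
#'   blue-to-red binned colours saturating above 12 s^-1).
#' @export
plot.contact_map <- function(x, ...) {
  nb <- 8L
  tab <- x$table
  tab$bin <- factor(bin_gamma2(tab$gamma2), levels = seq_len(nb))
  pal <- grDevices::colorRampPalette(c("#2166AC", "#92C5DE", "#F7F7F7",
                                       "#FDDBC7", "#D6604D", "#B2182B"))(nb)
  labs <- c("0", "0-2", "2-4", "4-6", "6-8", "8-10", "10-12", ">12")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$residue,
                                    y = factor(.data$spin_label_site),
                                    fill = .data$bin)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = setNames(pal, seq_len(nb)),
                               labels = setNames(labs, seq_len(nb)),
                               name = expression(Gamma[2] ~ (s^-1)),
                               drop = FALSE) +
    ggplot2::labs(x = "residue (visible chain)", y = "spin-label site") +
    ggplot2::theme_minimal()
}
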