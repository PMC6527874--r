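#' Passive membrane parameters
#'
#' Bundles the specific membrane capacitance, specific membrane resistance,
#' intracellular resistivity and leak reversal potential of a uniform passive
#' membrane. The leak conductance density is always derived as \code{1/Rm}
#' and never stored separately.
#'
#' @param Cm specific membrane capacitance, uF/cm^2 (default 1).
#' @param Rm specific membrane resistance, Ohm cm^2 (default 10000).
#' @param Ri intracellular resistivity, Ohm cm (default 110).
#' @param E_leak leak reversal potential, mV (default -81).
#' @return An object of class \code{passive_params}.
#' @examples
#' passive_params()
#' @export
passive_params <- function(Cm = 1, Rm = 10000, Ri = 110, E_leak = -81) {
  if (!is.numeric(Cm) || Cm <= 0) stop("Cm must be a positive number (uF/cm^2)")
  if (!is.numeric(Rm) || Rm <= 0) stop("Rm must be a positive number (Ohm cm^2)")
  if (!is.numeric(Ri) || Ri <= 0) stop("Ri must be a positive number (Ohm cm)")
  if (!is.finite(E_leak)) stop("E_leak must be finite (mV)")
  structure(list(Cm = Cm, Rm = Rm, Ri = Ri, E_leak = E_leak),
            class = "passive_params")
}

#' Lateral surface area of a cylindrical segment
#'
#' Computes the membrane area pi * d * L of a cylindrical segment. The soma
#' and the en passant boutons are represented as cylinders with length equal
#' to their diameter, so their membrane area follows the same formula.
#'
#' @param segment either a list / one-row data frame with elements
#'   \code{diameter} and \code{length} (um), or the diameter itself when
#'   \code{length} is given.
#' @param length segment length in um (only when \code{segment} is numeric).
#' @return Area in um^2.
#' @examples
#' surface_area(0.2, 1)           # thin axon segment
#' surface_area(list(diameter = 4, length = 4))  # bouton
#' @export
surface_area <- function(segment, length = NULL) {
  if (is.numeric(segment) && !is.null(length)) {
    d <- segment
    L <- length
  } else {
    d <- segment$diameter
    L <- segment$length
  }
  if (any(!is.finite(d)) || any(d <= 0)) stop("segment diameter must be positive")
  if (any(!is.finite(L)) || any(L <= 0)) stop("segment length must be positive")
  pi * d * L
}

#' Axial coupling conductance between two adjacent segments
#'
#' Series combination of the two half-segment axial resistances,
#' r = 4 * Ri * (L/2) / (pi * d^2) per half, each side using its own
#' geometry. Symmetric in the order of its arguments.
#'
#' @param seg_a,seg_b lists with elements \code{diameter} and \code{length}
#'   in um.
#' @param Ri intracellular resistivity, Ohm cm.
#' @return Conductance in uS.
#' @examples
#' seg <- list(diameter = 0.2, length = 1)
#' axial_conductance(seg, seg, Ri = 110)
#' @export
axial_conductance <- function(seg_a, seg_b, Ri) {
  if (Ri <= 0) stop("Ri must be positive")
  half_r <- function(s) {
    # Ri [Ohm cm] -> Ohm um; resistance of a half segment in Ohm
    4 * (Ri * 1e4) * (s$length / 2) / (pi * s$diameter^2)
  }
  r_ohm <- half_r(seg_a) + half_r(seg_b)
  1e6 / r_ohm   # 1/Ohm = S; -> uS
}

#' Infinite-cable length constant
#'
#' Closed-form steady-state length constant
#' \code{lambda = sqrt(Rm * d / (4 * Ri))} of an infinite uniform cable;
#' the boutons of the pearl-chain model load the cable and shorten the
#' effectively measured constant below this bound.
#'
#' @param Rm specific membrane resistance, Ohm cm^2.
#' @param Ri intracellular resistivity, Ohm cm.
#' @param diameter cable diameter, um.
#' @return Length constant in um.
#' @examples
#' lambda_infinite(10000, 110, 0.2)  # ~213 um for the mossy-fiber axon
#' @export
lambda_infinite <- function(Rm, Ri, diameter) {
  sqrt(Rm * (diameter * 1e-4) / (4 * Ri)) * 1e4
}

# Discretize one section into nseg equal cylindrical segments.
.discretize_section <- function(name, kind, length, diameter, gna, gk,
                                segments_per_um) {
  nseg <- max(1L, as.integer(round(length * segments_per_um)))
  seg_len <- length / nseg
  data.frame(section = name, kind = kind, seg = seq_len(nseg),
             length = seg_len, diameter = diameter,
             gna = gna, gk = gk, stringsAsFactors = FALSE)
}

.assemble_chain <- function(sections, passive, e_na, e_k, gating_scheme,
                            segments_per_um) {
  segs <- do.call(rbind, lapply(seq_len(nrow(sections)), function(i) {
    s <- sections[i, ]
    .discretize_section(s$section, s$kind, s$length, s$diameter,
                        s$gna, s$gk, segments_per_um)
  }))
  n <- nrow(segs)
  # axial position of each segment center, measured along the chain midline
  ends <- cumsum(segs$length)
  segs$x <- ends - segs$length / 2
  segs$area <- surface_area(segs$diameter, segs$length)
  segs$cm <- passive$Cm
  segs$gl <- 1000 / passive$Rm          # mS/cm^2
  segs$e_na <- e_na
  segs$e_k <- e_k
  segs$e_leak <- passive$E_leak

  g_ax <- vapply(seq_len(n - 1), function(i) {
    axial_conductance(list(diameter = segs$diameter[i], length = segs$length[i]),
                      list(diameter = segs$diameter[i + 1], length = segs$length[i + 1]),
                      passive$Ri)
  }, numeric(1))

  sections$start <- c(0, cumsum(sections$length)[-nrow(sections)])
  sections$end <- cumsum(sections$length)

  structure(list(segments = segs, g_axial_uS = g_ax, passive = passive,
                 sections = sections, gating_scheme = gating_scheme,
                 segments_per_um = as.numeric(segments_per_um)),
            class = "compartment_chain")
}

#' Build the mossy-fiber pearl-chain model
#'
#' Constructs the discretized compartment chain of a hippocampal mossy fiber:
#' a soma followed by strictly alternating thin axonal cylinders and large en
#' passant boutons (soma -> axon1 -> bouton1 -> ... -> axon10 -> bouton10).
#' Soma and boutons are represented as cylinders with length equal to their
#' diameter, preserving the membrane area exposed to the solver. The default
#' arguments reproduce the reference mossy-fiber model: Cm 1 uF/cm^2,
#' Rm 10000 Ohm cm^2, Ri 110 Ohm cm, soma diameter 10 um, ten 0.2 um x 100 um
#' axonal cylinders, ten 4 um boutons, Na+ conductance 50 mS/cm^2 in axon and
#' boutons and 10 mS/cm^2 in the soma, K+ conductance 36 mS/cm^2 everywhere,
#' E_Na +50 mV, E_K -85 mV, one segment per um.
#'
#' @param passive \code{\link{passive_params}} object.
#' @param n_boutons number of axon/bouton repeats.
#' @param soma_diameter soma diameter, um.
#' @param axon_diameter,axon_length axonal cylinder geometry, um.
#' @param bouton_diameter bouton diameter, um.
#' @param gna_axon,gna_soma Na+ conductance densities, mS/cm^2. A density of
#'   exactly 0 represents a knockout.
#' @param gk K+ conductance density, mS/cm^2 (uniform).
#' @param e_na,e_k equilibrium potentials, mV.
#' @param gating_scheme name of a registered gating scheme
#'   (see \code{\link{register_gating_scheme}}).
#' @param segments_per_um discretization density; boutons and soma get
#'   \code{max(1, round(length * segments_per_um))} segments.
#' @return An object of class \code{compartment_chain}.
#' @examples
#' chain <- build_mossy_fiber_model()
#' chain
#' @export
build_mossy_fiber_model <- function(passive = passive_params(),
                                    n_boutons = 10,
                                    soma_diameter = 10,
                                    axon_diameter = 0.2, axon_length = 100,
                                    bouton_diameter = 4,
                                    gna_axon = 50, gna_soma = 10, gk = 36,
                                    e_na = 50, e_k = -85,
                                    gating_scheme = "hh_mf",
                                    segments_per_um = 1) {
  geom <- c(soma_diameter = soma_diameter, axon_diameter = axon_diameter,
            axon_length = axon_length, bouton_diameter = bouton_diameter)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("non-positive geometry: ", paste(names(geom)[geom <= 0], collapse = ", "),
         " must be > 0")
  if (n_boutons < 1) stop("n_boutons must be >= 1")
  if (gna_axon < 0 || gna_soma < 0 || gk < 0)
    stop("conductance densities must be >= 0 (0 encodes a knockout)")

  rows <- list(data.frame(section = "soma", kind = "soma",
                          length = soma_diameter, diameter = soma_diameter,
                          gna = gna_soma, gk = gk, stringsAsFactors = FALSE))
  for (k in seq_len(n_boutons)) {
    rows[[length(rows) + 1]] <- data.frame(
      section = paste0("axon", k), kind = "axon",
      length = axon_length, diameter = axon_diameter,
      gna = gna_axon, gk = gk, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      section = paste0("bouton", k), kind = "bouton",
      length = bouton_diameter, diameter = bouton_diameter,
      gna = gna_axon, gk = gk, stringsAsFactors = FALSE)
  }
  sections <- do.call(rbind, rows)
  .assemble_chain(sections, passive, e_na, e_k, gating_scheme, segments_per_um)
}

#' Build a uniform single-cable chain
#'
#' Degenerate single-section chain (no soma, no boutons) used for analytic
#' validation of the solver against closed-form cable solutions; both ends
#' are sealed.
#'
#' @param length,diameter cable geometry, um.
#' @param passive \code{\link{passive_params}}.
#' @param gna,gk conductance densities, mS/cm^2 (default 0: passive cable).
#' @param e_na,e_k reversal potentials, mV.
#' @param gating_scheme registered gating scheme name.
#' @param segments_per_um discretization density.
#' @return A \code{compartment_chain} with a single section named "cable".
#' @export
build_single_cable <- function(length, diameter,
                               passive = passive_params(E_leak = -80),
                               gna = 0, gk = 0, e_na = 50, e_k = -85,
                               gating_scheme = "hh_mf", segments_per_um = 1) {
  if (length <= 0 || diameter <= 0) stop("non-positive geometry: cable length and diameter must be > 0")
  sections <- data.frame(section = "cable", kind = "axon",
                         length = length, diameter = diameter,
                         gna = gna, gk = gk, stringsAsFactors = FALSE)
  .assemble_chain(sections, passive, e_na, e_k, gating_scheme, segments_per_um)
}

#' @export
print.compartment_chain <- function(x, ...) {
  s <- x$segments
  cat("<compartment_chain> ", nrow(s), " segments, ",
      nrow(x$sections), " sections, total length ",
      format(sum(x$sections$length)), " um\n", sep = "")
  cat("  sections: ", paste(utils::head(x$sections$section, 4), collapse = ", "),
      if (nrow(x$sections) > 4) ", ...", "\n", sep = "")
  cat("  passive: Cm ", x$passive$Cm, " uF/cm^2, Rm ", x$passive$Rm,
      " Ohm cm^2, Ri ", x$passive$Ri, " Ohm cm, E_leak ",
      format(x$passive$E_leak), " mV\n", sep = "")
  cat("  gating scheme: ", x$gating_scheme, "\n", sep = "")
  invisible(x)
}

#' Map a named recording/stimulation site to a segment index
#'
#' \code{"soma"}, \code{"boutonK"} and \code{"axonK"} refer to the center
#' segment of the corresponding section; an integer is taken as a raw segment
#' index.
#'
#' @param chain a \code{compartment_chain}.
#' @param site site name or segment index.
#' @return Integer segment index (1-based).
#' @export
site_index <- function(chain, site) {
  if (is.numeric(site)) {
    i <- as.integer(site)
    if (i < 1 || i > nrow(chain$segments)) stop("segment index out of range: ", site)
    return(i)
  }
  idx <- which(chain$segments$section == site)
  if (length(idx) == 0)
    stop("unknown site '", site, "'; available sections: ",
         paste(chain$sections$section, collapse = ", "))
  idx[ceiling(length(idx) / 2)]
}

#' Chain end position of a section
#'
#' Distal end (um from the soma's proximal face) of a named section; used as
#' the origin of the distance coordinate when measuring passive decay beyond
#' the last active compartment.
#'
#' @param chain a \code{compartment_chain}.
#' @param section section name, e.g. \code{"bouton7"}.
#' @return Position in um.
#' @export
section_end <- function(chain, section) {
  i <- match(section, chain$sections$section)
  if (is.na(i)) stop("unknown section '", section, "'")
  chain$sections$end[i]
}

#' Sections of the chain from a given section to the distal end
#'
#' @param chain a \code{compartment_chain}.
#' @param from first section of the region (e.g. \code{"axon8"}).
#' @return Character vector of section names.
#' @export
sections_from <- function(chain, from) {
  i <- match(from, chain$sections$section)
  if (is.na(i)) stop("unknown section '", from, "'")
  chain$sections$section[i:nrow(chain$sections)]
}
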