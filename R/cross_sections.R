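# Embedded elemental photon interaction data (1-300 keV).
#
# One plain-text table per element under inst/extdata/xs/, with columns
# energy_keV, mu/rho photoelectric, incoherent, coherent and mu_en/rho
# (all cm^2/g).  Absorption edges are marked by "# edge <keV>" comment
# lines and the grid carries a pair of points straddling each edge, so
# interpolation never bridges an edge discontinuity.

.npder <- new.env(parent = emptyenv())

#' Elements with embedded cross-section tables
#'
#' @return Character vector of element symbols covered by the shipped
#'   photon cross-section tables.
#' @export
xs_elements <- function() {
  sort(sub("\\.txt$", "", dir(system.file("extdata", "xs", package = "npder"),
                              pattern = "\\.txt$")))
}

xs_table <- function(symbol) {
  key <- paste0("xs_", symbol)
  if (!is.null(.npder[[key]])) return(.npder[[key]])
  path <- system.file("extdata", "xs", paste0(symbol, ".txt"), package = "npder")
  if (!nzchar(path)) {
    stop("no cross-section table for element '", symbol, "'; available: ",
         paste(xs_elements(), collapse = ", "), call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- regmatches(hdr[1], regexec("Z=([0-9]+) atomic_mass=([0-9.]+)", hdr[1]))[[1]]
  edges <- as.numeric(sub("# edge ", "", hdr[startsWith(hdr, "# edge")]))
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           col.names = c("energy", "pe", "incoh", "coh", "mu_en"))
  tab <- list(
    symbol = symbol,
    Z = as.integer(meta[2]),
    atomic_mass = as.numeric(meta[3]),
    energy = dat$energy,
    pe = dat$pe, incoh = dat$incoh, coh = dat$coh, mu_en = dat$mu_en,
    edges = sort(edges),
    # segment id per grid point: rows strictly below the k-th edge belong
    # to segment k
    segment = findInterval(dat$energy, sort(edges), left.open = FALSE)
  )
  .npder[[key]] <- tab
  tab
}

#' Atomic data for an element
#'
#' @param symbol Element symbol (see [xs_elements()]).
#' @return List with `symbol`, `Z` (atomic number), `atomic_mass` (g/mol)
#'   and `edges` (absorption-edge energies in keV inside the table range).
#' @export
element_info <- function(symbol) {
  tab <- xs_table(symbol)
  tab[c("symbol", "Z", "atomic_mass", "edges")]
}

# Edge-aware log-log interpolation of one column of an elemental table.
# Queries are assigned to the inter-edge segment they fall in and are
# interpolated only against grid points of that segment (clamped at the
# segment ends), so the left/right limits at an edge are respected.
xs_lookup <- function(symbol, energy, column) {
  tab <- xs_table(symbol)
  if (any(energy < tab$energy[1] | energy > tab$energy[length(tab$energy)])) {
    stop("energy outside table coverage [", tab$energy[1], ", ",
         tab$energy[length(tab$energy)], "] keV for ", symbol, call. = FALSE)
  }
  y <- tab[[column]]
  out <- numeric(length(energy))
  seg_q <- findInterval(energy, tab$edges, left.open = FALSE)
  for (s in unique(seg_q)) {
    qi <- seg_q == s
    gi <- tab$segment == s
    xg <- log(tab$energy[gi])
    yg <- y[gi]
    pos <- yg > 0
    if (all(pos)) {
      out[qi] <- exp(stats::approx(xg, log(yg), xout = log(energy[qi]),
                                   rule = 2)$y)
    } else {
      out[qi] <- stats::approx(xg, yg, xout = log(energy[qi]), rule = 2)$y
    }
  }
  out
}
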