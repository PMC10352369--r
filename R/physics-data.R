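## Static atomic data: cross-section tables, element constants, emission
## lines.  Shipped as plain-text CSVs under inst/extdata/attenuation and
## loaded (and cached) on first use.

.xfi_cache <- new.env(parent = emptyenv())

.data_path <- function(...) {
  system.file("extdata", "attenuation", ..., package = "xfiquant",
              mustWork = TRUE)
}

.element_constants <- function() {
  if (is.null(.xfi_cache$elements)) {
    .xfi_cache$elements <- utils::read.csv(.data_path("elements.csv"),
                                           stringsAsFactors = FALSE)
  }
  .xfi_cache$elements
}

.emission_line_table <- function() {
  if (is.null(.xfi_cache$lines)) {
    .xfi_cache$lines <- utils::read.csv(.data_path("lines.csv"),
                                        stringsAsFactors = FALSE)
  }
  .xfi_cache$lines
}

.attenuation_raw <- function(symbol) {
  key <- paste0("att_", symbol)
  if (is.null(.xfi_cache[[key]])) {
    path <- system.file("extdata", "attenuation", paste0(symbol, ".csv"),
                        package = "xfiquant")
    if (!nzchar(path)) {
      stop("no attenuation table for element '", symbol, "'", call. = FALSE)
    }
    .xfi_cache[[key]] <- utils::read.csv(path)
  }
  .xfi_cache[[key]]
}

#' Emission lines of an element
#'
#' Returns the tabulated K-series emission lines for a marker element, with
#' line energies in keV and relative intensities that sum to one over the
#' listed lines.
#'
#' @param symbol Element symbol (currently `"I"` or `"Pd"` carry line data).
#' @return A data frame with columns `symbol`, `line`, `energy_keV`,
#'   `rel_intensity`.
#' @examples
#' emission_lines("I")
#' @export
emission_lines <- function(symbol) {
  tab <- .emission_line_table()
  out <- tab[tab$symbol == symbol, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no emission-line data for element '", symbol, "'", call. = FALSE)
  }
  out$rel_intensity <- out$rel_intensity / sum(out$rel_intensity)
  rownames(out) <- NULL
  out
}

#' Element constants
#'
#' Atomic constants used throughout the package: atomic number, molar mass
#' (g/mol), K-edge energy (keV), K fluorescence yield and K-shell absorption
#' jump factor.
#'
#' @param symbol Element symbol, e.g. `"I"`.
#' @return A list of class `xfi_element` including the K emission lines when
#'   tabulated.
#' @examples
#' element_data("Pd")$k_edge_keV
#' @export
element_data <- function(symbol) {
  tab <- .element_constants()
  row <- tab[tab$symbol == symbol, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("unknown element '", symbol, "'", call. = FALSE)
  }
  lines <- if (symbol %in% .emission_line_table()$symbol) {
    emission_lines(symbol)
  } else {
    NULL
  }
  structure(list(symbol = symbol, z = row$z, molar_mass = row$molar_mass,
                 k_edge_keV = row$k_edge_keV, omega_k = row$omega_k,
                 k_jump = row$k_jump, lines = lines),
            class = "xfi_element")
}

#' @export
print.xfi_element <- function(x, ...) {
  cat(sprintf("<xfi_element> %s (Z=%d, M=%.3f g/mol, K-edge %.4f keV)\n",
              x$symbol, x$z, x$molar_mass, x$k_edge_keV))
  if (!is.null(x$lines)) {
    cat(sprintf("  omega_K = %.3f, K jump = %.2f\n", x$omega_k, x$k_jump))
    for (i in seq_len(nrow(x$lines))) {
      cat(sprintf("  %-4s %7.3f keV  (%.3f)\n", x$lines$line[i],
                  x$lines$energy_keV[i], x$lines$rel_intensity[i]))
    }
  }
  invisible(x)
}

#' Define a material
#'
#' A material is a named set of elemental mass fractions plus a bulk density.
#' Fractions must be non-negative and sum to one.
#'
#' @param name Material name.
#' @param fractions Named numeric vector of elemental mass fractions.
#' @param density_g_cm3 Bulk density in g/cm^3.
#' @return An object of class `xfi_material`.
#' @examples
#' xfi_material("water", c(H = 0.1119, O = 0.8881), 1.0)
#' @export
xfi_material <- function(name, fractions, density_g_cm3) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (any(fractions < 0)) {
    stop("mass fractions must be non-negative", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", sum(fractions), ")",
         call. = FALSE)
  }
  if (!is.numeric(density_g_cm3) || density_g_cm3 <= 0) {
    stop("density must be positive", call. = FALSE)
  }
  known <- .element_constants()$symbol
  bad <- setdiff(names(fractions), known)
  if (length(bad)) {
    stop("no data for element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, fractions = fractions,
                 density = density_g_cm3),
            class = "xfi_material")
}

#' @export
print.xfi_material <- function(x, ...) {
  cat(sprintf("<xfi_material> %s (rho = %.4g g/cm^3): %s\n", x$name,
              x$density,
              paste(sprintf("%s %.4f", names(x$fractions), x$fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Built-in materials
#'
#' Convenience constructor for the bulk materials used in phantom and
#' detector modelling: `"water"`, `"soft_tissue"` (ICRU-44-like four-element
#' mix), `"pmma"` (Plexiglass), `"silicon"` and `"air"`.
#'
#' @param name One of the built-in material names.
#' @return An `xfi_material`.
#' @examples
#' builtin_material("water")
#' @export
builtin_material <- function(name = c("water", "soft_tissue", "pmma",
                                      "silicon", "air")) {
  name <- match.arg(name)
  switch(name,
    water = xfi_material("water", c(H = 0.1119, O = 0.8881), 1.0),
    soft_tissue = {
      f <- c(H = 0.102, C = 0.143, N = 0.034, O = 0.708)
      xfi_material("soft_tissue", f / sum(f), 1.06)
    },
    pmma = xfi_material("pmma", c(H = 0.0805, C = 0.5999, O = 0.3196), 1.19),
    silicon = xfi_material("silicon", c(Si = 1), 2.33),
    air = xfi_material("air", c(N = 0.7655, O = 0.2345), 1.205e-3)
  )
}
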