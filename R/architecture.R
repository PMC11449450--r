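#' Muscle architecture record
#'
#' @param name Muscle name.
#' @param mass_g Muscle mass (g, > 0).
#' @param fibre_lengths_mm Fibre length measurements (mm, > 0); PCSA uses
#'   their mean.
#' @param muscle_length_mm Whole-muscle length (mm), optional (needed for
#'   [fibre_muscle_ratio()]).
#' @param pennation_deg Pennation angle of the fibres relative to the line
#'   of action (degrees, in \[0, 90)).
#' @param density Muscle density (g mm^-3), default 0.001056.
#' @return An object of class `muscle_architecture`.
#' @export
muscle_architecture <- function(name, mass_g, fibre_lengths_mm,
                                muscle_length_mm = NA_real_,
                                pennation_deg = 0, density = 0.001056) {
  stopifnot(is.finite(mass_g), mass_g > 0,
            all(is.finite(fibre_lengths_mm)), all(fibre_lengths_mm > 0),
            is.finite(pennation_deg), pennation_deg >= 0, density > 0)
  if (pennation_deg >= 90) {
    stop("pennation angle must be below 90 degrees", call. = FALSE)
  }
  structure(list(name = as.character(name), mass_g = mass_g,
                 fibre_lengths_mm = as.numeric(fibre_lengths_mm),
                 muscle_length_mm = muscle_length_mm,
                 pennation_deg = pennation_deg, density = density),
            class = "muscle_architecture")
}

#' Physiological cross-sectional area
#'
#' `PCSA = M cos(theta) / (rho * Lf)` with muscle mass M (g), pennation
#' angle theta, density rho (g mm^-3) and mean fibre length Lf (mm);
#' result in mm^2. PCSA is proportional to the muscle's maximal force
#' capacity.
#'
#' @param arch A [muscle_architecture()].
#' @return PCSA in mm^2.
#' @examples
#' dig <- muscle_architecture("digastric", mass_g = 0.691,
#'                            fibre_lengths_mm = 11.59,
#'                            pennation_deg = 9.81)
#' pcsa(dig)  # ~55.6 mm^2 = 0.556 cm^2
#' @export
pcsa <- function(arch) {
  stopifnot(inherits(arch, "muscle_architecture"))
  lf <- mean(arch$fibre_lengths_mm)
  arch$mass_g * cos(arch$pennation_deg * pi / 180) / (arch$density * lf)
}

#' Fibre length to muscle length ratio
#'
#' Mean fibre length divided by whole-muscle length; long-fibred muscles
#' (ratio near 1) favour displacement, short-fibred pennate muscles favour
#' force.
#'
#' @param arch A [muscle_architecture()] with `muscle_length_mm` set.
#' @return The ratio (fraction).
#' @export
fibre_muscle_ratio <- function(arch) {
  stopifnot(inherits(arch, "muscle_architecture"))
  if (!is.finite(arch$muscle_length_mm) || arch$muscle_length_mm <= 0) {
    stop("muscle length must be positive", call. = FALSE)
  }
  mean(arch$fibre_lengths_mm) / arch$muscle_length_mm
}

#' Architecture morphospace classification
#'
#' Places each muscle in the fibre-length x PCSA morphospace and assigns a
#' functional specialisation by a within-set split (median by default):
#' relatively long fibres with low PCSA are displacement specialised, short
#' fibres with high PCSA force specialised, long fibres with high PCSA
#' power specialised, and the remaining (short, low) quadrant is
#' unspecialised. The split is relative, so the classification is invariant
#' to a common rescaling of all PCSAs or all fibre lengths.
#'
#' @param muscles A list of [muscle_architecture()] objects (at least 2).
#' @param threshold Split rule: `"median"` (default), `"mean"`, or a
#'   numeric `c(fibre_length_mm, pcsa_mm2)` pair of user-set split points.
#' @return A data frame with `muscle`, `fibre_length_mm`, `pcsa_mm2`,
#'   `label`; the split points are attached as attribute `split`.
#' @export
morphospace_classify <- function(muscles, threshold = "median") {
  if (!is.list(muscles) || length(muscles) < 2L) {
    stop("morphospace classification needs at least 2 muscles", call. = FALSE)
  }
  fl <- vapply(muscles, function(m) mean(m$fibre_lengths_mm), numeric(1))
  pc <- vapply(muscles, pcsa, numeric(1))
  split <- if (is.numeric(threshold)) {
    stopifnot(length(threshold) == 2L)
    threshold
  } else if (identical(threshold, "median")) {
    c(stats::median(fl), stats::median(pc))
  } else if (identical(threshold, "mean")) {
    c(mean(fl), mean(pc))
  } else {
    stop("threshold must be 'median', 'mean' or a numeric pair",
         call. = FALSE)
  }
  long <- fl > split[1]
  high <- pc > split[2]
  label <- ifelse(long & !high, "displacement",
                  ifelse(!long & high, "force",
                         ifelse(long & high, "power", "unspecialised")))
  out <- data.frame(
    muscle = vapply(muscles, function(m) m$name, character(1)),
    fibre_length_mm = fl, pcsa_mm2 = pc, label = label,
    stringsAsFactors = FALSE)
  attr(out, "split") <- c(fibre_length_mm = split[1], pcsa_mm2 = split[2])
  out
}

#' Read a muscle architecture table from CSV
#'
#' Expected columns: `muscle`, `mass_g`, `muscle_length_mm`,
#' `pennation_deg`, and one or more `fibre_length_mm` columns (e.g.
#' `fibre_length_mm`, `fibre_length_mm_2`, ...).
#'
#' @param path CSV file path.
#' @return A list of [muscle_architecture()] objects.
#' @export
read_architecture_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  flcols <- grep("^fibre_length_mm", names(df), value = TRUE)
  if (!length(flcols)) stop("no fibre_length_mm column(s)", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    muscle_architecture(
      name = df$muscle[i], mass_g = df$mass_g[i],
      fibre_lengths_mm = as.numeric(df[i, flcols]),
      muscle_length_mm = if ("muscle_length_mm" %in% names(df)) {
        df$muscle_length_mm[i]
      } else NA_real_,
      pennation_deg = if ("pennation_deg" %in% names(df)) {
        df$pennation_deg[i]
      } else 0)
  })
}
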