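# Orthonormal wavelet filter banks: Daubechies Extremal Phase (D),
# Daubechies Least Asymmetric (LA), and Coiflet (C) families.
#
# Scaling filters are tabulated at double precision in the Percival & Walden
# (WMTSA) time-domain convention; the wavelet filter is obtained from the
# quadrature-mirror relation h[l] = (-1)^l g[L-1-l].

.scaling_filters <- list(
  "D2" = c(
      0.70710678118654757, 0.70710678118654757),
  "D4" = c(
      0.48296291314453416, 0.83651630373780794, 0.22414386804201339, -0.12940952255126037),
  "D6" = c(
      0.33267055295008263, 0.80689150931109255, 0.45987750211849154, -0.13501102001025458,
      -0.085441273882026658, 0.035226291885709533),
  "D8" = c(
      0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854,
      -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
  "D10" = c(
      0.16010239797419293, 0.60382926979718965, 0.72430852843777294, 0.13842814590132074,
      -0.24229488706638203, -0.032244869584638375, 0.077571493840045719, -0.0062414902127982744,
      -0.012580751999081999, 0.0033357252854737712),
  "D12" = c(
      0.11154074335010947, 0.49462389039845306, 0.75113390802109536, 0.31525035170919763,
      -0.22626469396543983, -0.12976686756726194, 0.097501605587323043, 0.027522865530305727,
      -0.03158203931748603, 0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
  "D14" = c(
      0.077852054085009184, 0.39653931948191729, 0.72913209084623509, 0.46978228740519312,
      -0.14390600392856498, -0.22403618499387498, 0.071309219266830259, 0.080612609151083078,
      -0.038029936935014413, -0.016574541630666881, 0.01255099855609984, 0.00042957797292136651,
      -0.0018016407040474908, 0.00035371379997452024),
  "D16" = c(
      0.054415842243104008, 0.31287159091429995, 0.67563073629728976, 0.58535468365420673,
      -0.015829105256349306, -0.28401554296154691, 0.00047248457391328279, 0.12874742662047847,
      -0.017369301001807547, -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
      -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933, -0.00011747678412476953),
  "D18" = c(
      0.038077947363878345, 0.24383467461259034, 0.60482312369011115, 0.65728807805130052,
      0.13319738582500756, -0.29327378327917492, -0.096840783222976456, 0.14854074933810638,
      0.03072568147933338, -0.067632829061329974, 0.00025094711483145197, 0.022361662123679096,
      -0.0047232047577513972, -0.0042815036824634303, 0.0018476468830562265, 0.00023038576352319597,
      -0.00025196318894271012, 3.9347320316271603e-05),
  "D20" = c(
      0.026670057900555554, 0.1881768000776915, 0.52720118893172563, 0.68845903945360354,
      0.28117234366057747, -0.24984642432731538, -0.19594627437737705, 0.12736934033579325,
      0.093057364603572348, -0.071394147166397082, -0.029457536821875813, 0.033212674059341002,
      0.0036065535669561697, -0.010733175483330575, 0.0013953517470529011, 0.0019924052951850561,
      -0.00068585669495971162, -0.00011646685512928545, 9.3588670320069592e-05, -1.3264202894521244e-05),
  "LA8" = c(
      -0.075765714789273325, -0.02963552764599851, 0.49761866763201545, 0.80373875180591614,
      0.29785779560527736, -0.099219543576847216, -0.012603967262037833, 0.032223100604042702),
  "LA10" = c(
      0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936,
      0.72340769040242059, 0.63397896345821192, 0.016602105764522319, -0.17532808990845047,
      -0.021101834024758855, 0.019538882735286728),
  "LA12" = c(
      0.015404109327027373, 0.0034907120842174702, -0.11799011114819057, -0.048311742585632998,
      0.49105594192674662, 0.787641141030194, 0.3379294217276218, -0.072637522786462516,
      -0.021060292512300564, 0.044724901770665779, 0.0017677118642428036, -0.007800708325034148),
  "LA14" = c(
      0.0026818145682578781, -0.0010473848886829163, -0.01263630340325193, 0.03051551316596357,
      0.067892693501372697, -0.049552834937127255, 0.017441255086855827, 0.5361019170917628,
      0.76776431700316405, 0.28862963175151463, -0.14004724044296152, -0.10780823770381774,
      0.0040102448715336634, 0.010268176708511255),
  "LA16" = c(
      -0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981, 0.0076074873249176054,
      -0.14329423835080971, -0.061273359067658524, 0.48135965125837221, 0.77718575170052351,
      0.3644418948353314, -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
      0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668, 0.0018899503327594609),
  "LA18" = c(
      0.0014009155259146807, 0.00061978088898558676, -0.013271967781817119, -0.01152821020767923,
      0.03022487885827568, 0.00058346274612580684, -0.054568958430834071, 0.238760914607303,
      0.717897082764412, 0.61733844914093583, 0.035272488035271894, -0.19155083129728512,
      -0.018233770779395985, 0.06207778930288603, 0.0088592674934004842, -0.010264064027633142,
      -0.00047315449868008311, 0.0010694900329086053),
  "LA20" = c(
      0.00077015980911449011, 9.5632670722894754e-05, -0.0086412992770224222, -0.0014653825813050513,
      0.045927239231092203, 0.011609893903711381, -0.15949427888491757, -0.070880535783243853,
      0.47169066693843925, 0.7695100370211071, 0.38382676106708546, -0.035536740473817552,
      -0.0319900568824278, 0.049994972077376687, 0.0057649120335819086, -0.02035493981231129,
      -0.00080435893201654491, 0.0045931735853118284, 5.7036083618494284e-05, -0.00045932942100465878),
  "C6" = c(
      -0.015655728135791993, -0.07273261951252645, 0.38486484686485778, 0.85257202021160039,
      0.33789766245748182, -0.07273261951252645),
  "C12" = c(
      -0.00072054944552034698, -0.0018232088709110323, 0.0056114348193688343, 0.02368017194684777,
      -0.059434418646431092, -0.076488599078280761, 0.41700518442323908, 0.81272363544941351,
      0.38611006682276289, -0.067372554723725595, -0.041464936786871777, 0.016387336463203641),
  "C18" = c(
      -3.4599773197272781e-05, -7.0983302506379004e-05, 0.00046621695982040288, 0.0011175187708306303,
      -0.0025745176881367972, -0.0090079761367306242, 0.015880544863669452, 0.034555027573297738,
      -0.082301927106299827, -0.071799821619154838, 0.42848347637737, 0.79377722262608719,
      0.40517690240911824, -0.061123390002972552, -0.065771911281469364, 0.023452696142077168,
      0.0077825964256727463, -0.0037935128643808019),
  "C24" = c(
      -1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05, 6.2338854312787192e-05,
      -0.00025997433712225682, -0.00058902022463321654, 0.0012665610789256603, 0.0037514346971460866,
      -0.0056582838001308835, -0.015211728187697211, 0.025082253337949612, 0.039334422605589149,
      -0.096220424535952642, -0.066627472366817167, 0.43438603311435653, 0.78223893442428261,
      0.41530842700068227, -0.056077319603569258, -0.081266710249193727, 0.02668230466960483,
      0.016068947131575029, -0.0073461679362680507, -0.001629492425226786, 0.00089231390253700297)
)

#' Admissible wavelet filters
#'
#' The three orthonormal, compactly supported filter families supported by
#' the package and the lengths at which each is defined: Daubechies Extremal
#' Phase (`"D"`, lengths 2, 4, ..., 20), Daubechies Least Asymmetric
#' (`"LA"`, lengths 8, 10, ..., 20) and Coiflet (`"C"`, lengths 6, 12, 18,
#' 24). The LA family requires length >= 8 and Coiflets exist only at
#' multiples of 6.
#'
#' @return A data frame with columns `family`, `length` and `name`
#'   (e.g. `"D4"`), one row per admissible filter.
#' @export
#' @examples
#' admissible_filters()
admissible_filters <- function() {
  nm <- names(.scaling_filters)
  fam <- sub("[0-9]+$", "", nm)
  len <- as.integer(sub("^[A-Z]+", "", nm))
  data.frame(family = fam, length = len, name = nm, stringsAsFactors = FALSE)
}

#' Construct an orthonormal wavelet filter
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) coefficient pair
#' for one member of the Daubechies Extremal Phase, Least Asymmetric, or
#' Coiflet family, in the Percival & Walden time-domain convention. The
#' wavelet filter is derived from the scaling filter by the quadrature
#' mirror relation `h[l] = (-1)^l g[L-1-l]`, and the pair is validated
#' against the orthonormality identities (`sum(g) = sqrt(2)`, `sum(h) = 0`,
#' unit energy, orthogonality to even shifts) before it is returned.
#'
#' @param family One of `"D"`, `"LA"`, `"C"` (Daubechies Extremal Phase,
#'   Daubechies Least Asymmetric, Coiflet), or a combined name such as
#'   `"LA8"` with `length` missing.
#' @param length Even filter length; must be admissible for the family (see
#'   [admissible_filters()]).
#' @return An object of class `"wavelet_filter"`: a list with elements
#'   `family`, `length`, `name`, `g` (scaling coefficients) and `h`
#'   (wavelet coefficients).
#' @export
#' @examples
#' f <- wavelet_filter("D", 4)
#' sum(f$g^2)   # 1
#' sum(f$h)     # 0
wavelet_filter <- function(family, length = NULL) {
  if (is.null(length) && grepl("^(D|LA|C)[0-9]+$", family)) {
    length <- as.integer(sub("^[A-Z]+", "", family))
    family <- sub("[0-9]+$", "", family)
  }
  family <- match.arg(family, c("D", "LA", "C"))
  length <- as.integer(length)
  name <- paste0(family, length)
  if (!name %in% names(.scaling_filters)) {
    adm <- admissible_filters()
    stop(sprintf(
      "unsupported filter %s: admissible lengths are D in {%s}, LA in {%s}, C in {%s}",
      name,
      paste(adm$length[adm$family == "D"], collapse = ","),
      paste(adm$length[adm$family == "LA"], collapse = ","),
      paste(adm$length[adm$family == "C"], collapse = ",")
    ), call. = FALSE)
  }
  g <- .scaling_filters[[name]]
  L <- length
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  wf <- structure(
    list(family = family, length = L, name = name, g = g, h = h),
    class = "wavelet_filter"
  )
  .validate_filter(wf)
  wf
}

# Run-time validation of the filter-algebra identities (tolerance 1e-10;
# the tables are shipped constants, so a failure here means corruption).
.validate_filter <- function(wf, tol = 1e-10) {
  g <- wf$g; h <- wf$h; L <- wf$length
  stopifnot(L %% 2 == 0, length(g) == L)
  err <- c(
    abs(sum(g) - sqrt(2)),
    abs(sum(h)),
    abs(sum(g^2) - 1),
    abs(sum(h^2) - 1)
  )
  for (k in seq_len(L / 2 - 1)) {
    err <- c(err, abs(sum(g[seq_len(L - 2 * k)] * g[seq_len(L - 2 * k) + 2 * k])))
  }
  if (any(err > tol)) {
    stop("filter ", wf$name, " fails orthonormality validation", call. = FALSE)
  }
  invisible(wf)
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat(sprintf("Wavelet filter %s (%s family, length %d)\n", x$name,
              switch(x$family, D = "Daubechies Extremal Phase",
                     LA = "Daubechies Least Asymmetric", C = "Coiflet"),
              x$length))
  cat("scaling (g):", format(x$g, digits = 6), "\n")
  cat("wavelet (h):", format(x$h, digits = 6), "\n")
  invisible(x)
}

#' Number of vanishing moments of a wavelet filter
#'
#' Computes the largest `p` such that the discrete moments
#' `sum_l l^m h[l]` vanish for all `m = 0, ..., p-1`. A filter with `p`
#' vanishing moments annihilates polynomial trends up to degree `p - 1`,
#' which governs its denoising and detrending behaviour. For the D and LA
#' families this equals `length/2`; Coiflets of length `6K` have `2K`
#' wavelet vanishing moments.
#'
#' @param filter A [wavelet_filter()].
#' @param tol Absolute tolerance on the (scale-normalized) moment sums.
#' @return Integer count of vanishing moments.
#' @export
#' @examples
#' vanishing_moments(wavelet_filter("D", 8))  # 4
#' vanishing_moments(wavelet_filter("C", 6))  # 2
vanishing_moments <- function(filter, tol = 1e-8) {
  stopifnot(inherits(filter, "wavelet_filter"))
  h <- filter$h
  l <- seq_along(h) - 1
  p <- 0L
  for (m in 0:(length(h) - 1)) {
    mom <- sum(l^m * h)
    # normalize by the magnitude of the summands so long filters with large
    # l^m values are judged on relative cancellation
    ref <- max(sum(abs(l^m * h)), 1)
    if (abs(mom) / ref > tol) break
    p <- p + 1L
  }
  p
}

#' Squared-gain transfer functions of a filter pair
#'
#' Evaluates `|G(f)|^2` and `|H(f)|^2` for the scaling and wavelet filters
#' on a frequency grid. For an orthonormal pair these satisfy
#' `|G(f)|^2 + |H(f)|^2 = 2` everywhere.
#'
#' @param filter A [wavelet_filter()].
#' @param freqs Frequencies in cycles/sample at which to evaluate (default a
#'   regular grid on `[0, 0.5]`).
#' @return A data frame with columns `freq`, `gain_g`, `gain_h`.
#' @export
filter_gain <- function(filter, freqs = seq(0, 0.5, length.out = 257)) {
  stopifnot(inherits(filter, "wavelet_filter"))
  l <- seq_along(filter$g) - 1
  G <- vapply(freqs, function(f) Mod(sum(filter$g * exp(-2i * pi * f * l)))^2, 0)
  H <- vapply(freqs, function(f) Mod(sum(filter$h * exp(-2i * pi * f * l)))^2, 0)
  data.frame(freq = freqs, gain_g = G, gain_h = H)
}

#' Export filter coefficients as delimited text
#'
#' Writes a two-column (index, value) tab-separated table for audit, one
#' file per filter, containing the scaling or wavelet coefficients.
#'
#' @param filter A [wavelet_filter()].
#' @param path Output file path.
#' @param which `"scaling"` or `"wavelet"`.
#' @return The path, invisibly.
#' @export
export_filter <- function(filter, path, which = c("scaling", "wavelet")) {
  stopifnot(inherits(filter, "wavelet_filter"))
  which <- match.arg(which)
  v <- if (which == "scaling") filter$g else filter$h
  utils::write.table(
    data.frame(index = seq_along(v) - 1L, value = format(v, digits = 17)),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
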