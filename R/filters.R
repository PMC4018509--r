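# Orthonormal Daubechies scaling filters, normalized to sum(h) = sqrt(2).
# dbN has 2N taps and N vanishing moments; db1 is the Haar filter.
.db_lowpass <- list(
  db1 = c(7.0710678118654757e-01, 7.0710678118654757e-01),
  db2 = c(-1.2940952255126037e-01, 2.2414386804201339e-01,
          8.3651630373780794e-01, 4.8296291314453416e-01),
  db3 = c(3.5226291885709533e-02, -8.5441273882026658e-02,
          -1.3501102001025458e-01, 4.5987750211849154e-01,
          8.0689150931109255e-01, 3.3267055295008263e-01),
  db4 = c(-1.0597401785069032e-02, 3.2883011666885197e-02,
          3.0841381835560764e-02, -1.8703481171909309e-01,
          -2.7983769416859854e-02, 6.3088076792985892e-01,
          7.1484657055291567e-01, 2.3037781330889651e-01),
  db5 = c(3.3357252854737712e-03, -1.2580751999081999e-02,
          -6.2414902127982744e-03, 7.7571493840045719e-02,
          -3.2244869584638375e-02, -2.4229488706638203e-01,
          1.3842814590132074e-01, 7.2430852843777294e-01,
          6.0382926979718965e-01, 1.6010239797419293e-01),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03,
          5.5384220116149613e-04, -3.1582039317486030e-02,
          2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01,
          3.1525035170919763e-01, 7.5113390802109536e-01,
          4.9462389039845306e-01, 1.1154074335010947e-01),
  db7 = c(3.5371379997452024e-04, -1.8016407040474908e-03,
          4.2957797292136651e-04, 1.2550998556099840e-02,
          -1.6574541630666881e-02, -3.8029936935014413e-02,
          8.0612609151083078e-02, 7.1309219266830259e-02,
          -2.2403618499387498e-01, -1.4390600392856498e-01,
          4.6978228740519312e-01, 7.2913209084623509e-01,
          3.9653931948191729e-01, 7.7852054085009184e-02),
  db8 = c(-1.1747678412476953e-04, 6.7544940645056933e-04,
          -3.9174037337694705e-04, -4.8703529934515741e-03,
          8.7460940474057766e-03, 1.3981027917398282e-02,
          -4.4088253930794755e-02, -1.7369301001807547e-02,
          1.2874742662047847e-01, 4.7248457391328279e-04,
          -2.8401554296154691e-01, -1.5829105256349306e-02,
          5.8535468365420673e-01, 6.7563073629728976e-01,
          3.1287159091429995e-01, 5.4415842243104008e-02)
)

#' Wavelet filter banks for the stationary transform
#'
#' Returns the analysis/synthesis taps of an orthonormal Daubechies wavelet.
#' The high-pass analysis filter is the quadrature mirror
#' g0[k] = (-1)^k h0[L-1-k]; the synthesis filters are the time-reversed
#' analysis filters, which for an orthonormal bank yields perfect
#' reconstruction of the undecimated transform.
#'
#' @param name one of "haar" (alias of "db1"), "db1" .. "db8".
#' @return a \linkS4class{FilterBank}.
#' @examples
#' waveletFilters("haar")
#' sum(waveletFilters("db4")@h0^2)  # unit energy
#' @export
waveletFilters <- function(name = "haar") {
  name <- tolower(name)
  key <- if (name == "haar") "db1" else name
  h0 <- .db_lowpass[[key]]
  if (is.null(h0))
    stop("unknown wavelet family '", name, "'; supported: haar, db1..db8")
  L <- length(h0)
  g0 <- (-1)^(seq_len(L) - 1) * rev(h0)
  new("FilterBank", h0 = h0, g0 = g0, h1 = rev(h0), g1 = rev(g0),
      name = name)
}
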