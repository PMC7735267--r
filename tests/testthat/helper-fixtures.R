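# Shared fixtures built in code.

# Independent Mercator closed-form loxodrome bearing, used as the oracle for
# rhumb_bearing (kept deliberately separate from the package implementation).
oracle_rhumb_bearing <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  psi <- function(lat) log(tan(pi / 4 + lat * rad / 2))
  dlon <- ((lon2 - lon1 + 180) %% 360 - 180) * rad
  (atan2(dlon, psi(lat2) - psi(lat1)) / rad) %% 360
}

# Direct evaluation of the Fisher-Lee double-sum formula.
oracle_fisher_lee <- function(a, b) {
  ar <- a * pi / 180; br <- b * pi / 180
  n <- length(a); num <- d1 <- d2 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    num <- num + sin(ar[i] - ar[j]) * sin(br[i] - br[j])
    d1 <- d1 + sin(ar[i] - ar[j])^2
    d2 <- d2 + sin(br[i] - br[j])^2
  }
  num / sqrt(d1 * d2)
}

# Noiseless grouped cline data from known parameters.
noiseless_groups <- function(params, lons = sort(c(seq(12, 16, length.out = 20),
                                                   seq(13.5, 14.5, length.out = 20))),
                             n = 4) {
  data.frame(position = lons, mean_trait = cline_mean(lons, params),
             sd_trait = 0, n = n)
}

# Synthetic linear equatorial track: lon 0 -> 10 over days 0..10.
equator_track <- function(start = as.Date("2015-09-01")) {
  data.frame(bird_id = "eq1", date = start + 0:10, lat = 0, lon = 0:10)
}
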