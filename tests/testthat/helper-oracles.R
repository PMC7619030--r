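# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances go through 3-d chord geometry, n-grams
# through a nested-loop enumeration, REML through a dense multivariate-normal
# likelihood, and FNV-1a through a frozen table computed with an unrelated
# implementation.

# central-angle (chord / acos) great-circle oracle
oracle_haversine <- function(lat1, lon1, lat2, lon2, radius_km) {
  to_xyz <- function(lat, lon) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  d <- sum(to_xyz(lat1, lon1) * to_xyz(lat2, lon2))
  radius_km * acos(max(-1, min(1, d)))
}

# brute-force n-gram enumeration over the wrapped word
oracle_ngrams <- function(word, minn, maxn) {
  w <- paste0("<", word, ">")
  out <- character(0)
  for (len in minn:maxn) {
    if (len > nchar(w)) next
    for (s in 1:(nchar(w) - len + 1)) {
      out <- c(out, substr(w, s, s + len - 1))
    }
  }
  out
}

# brute-force subword composition (enumerate, hash, sum)
oracle_oov <- function(word, table) {
  grams <- oracle_ngrams(word, table$minn, table$maxn)
  v <- numeric(ncol(table$buckets))
  for (g in grams) {
    v <- v + table$buckets[(fnv1a32(g) %% table$bucket_count) + 1, ]
  }
  unname(v)
}

# dense REML -2 log-likelihood for y = X b + Z1 a + Z2 c + e
oracle_reml_deviance <- function(y, X, id1, id2, s1, s2, se) {
  n <- length(y)
  Z1 <- stats::model.matrix(~ 0 + factor(id1))
  V <- se * diag(n) + s1 * tcrossprod(Z1)
  if (!is.null(id2)) {
    Z2 <- stats::model.matrix(~ 0 + factor(id2))
    V <- V + s2 * tcrossprod(Z2)
  }
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% b
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  ldV <- 2 * sum(log(diag(ch)))
  ldX <- determinant(XtViX, logarithm = TRUE)$modulus
  p <- ncol(X)
  as.numeric(ldV + ldX + crossprod(r, Vi_r) + (n - p) * log(2 * pi))
}

# FNV-1a 32-bit reference hashes (frozen from an independent implementation)
fnv_reference <- stats::setNames(c(2166136261, 3826002220), c("", "a"))
fnv_reference <- c(fnv_reference, c(
  "ab" = 1294271946,
  "Angel" = 883765898, "<Ange" = 3883870624, "ngel>" = 577698607,
  "Elephant & Castle" = 441147374, "nord" = 2894801972,
  "hbVrpoiVgRV" = 355856390, "fLBcbfnoG" = 2422421724,
  "bJmTPSIAoC" = 493400233, "rZ-aWZkSBv" = 3029658568,
  "jnWvg" = 3362403801, "yg" = 1516220777, "'wMqZc" = 2369582150,
  "DIhñyfJs&ONé" = 3817517109, "KmTecQ" = 1327971030,
  "Xsf'" = 579058859, "-gyr" = 1942464042, "O&xkxwnQ" = 2018068125,
  "SñRPe" = 132563923, "OkIUpkDyrñ" = 3291781043,
  "SJoRu&XXdo " = 2382235397, "Z" = 3742114125,
  "zrenüà" = 3890781934, "éTunPFzéüP" = 1779344549,
  "jqipVJIq" = 3111753683, "LBèLzxoiGFfW" = 133372612,
  "-" = 671913016, "jO" = 2185206966, "YRB" = 3795487440,
  "eyyMDHqJ-à" = 2541020654, "R" = 3607893173,
  "hRéIWrXPvhsB" = 2669161524, "DaU" = 1565803033,
  "qGWlGüg-Ot&O" = 4033250880, "MmjxWkIXñ" = 171471610,
  "üaMuFbhñx" = 2322685243, "pdpéK" = 1645217872,
  "fU" = 941794852, " eWIXiiQ" = 3531103731,
  "àJkqH-MB" = 2606589824, "ñIWU" = 3204518576,
  "mTtzQPxCèHCh" = 1281364392, "oevb" = 1463791285,
  "JoLoaeTOdo" = 3051215329, "èc" = 3969064503,
  "eGprQF" = 1084228844, "IiUñ" = 495786090,
  "KEpYEZAmgg" = 2934774977, "BwBAD-UdRPP" = 2083091429,
  "dz" = 1327282731, "vZ-gpmmICiBl" = 1998830922,
  "Dp-ñe" = 2214486339, "Z-'JgdPI" = 1957785145, "f" = 3809224601,
  "kAFE" = 3162715952, "-zèd" = 2643929859, "yay" = 1621745474,
  "ñYYDs" = 3949069242, "SUYJQTF" = 154704011, "msn" = 3917507885,
  "L" = 3373006507, "IdVuddLEGü'H" = 2209214967, "dGf" = 4121127886,
  "eMe" = 2077913270, "-pzhàéKpLMc" = 2000933438,
  "fAQLKHuñqn" = 382529582, "TupqziQPtDu" = 2113059872,
  "aD" = 1730490040, "KgeInGqiñw" = 3470433013,
  "ép" = 3818213027, "skC&IT" = 1223934151, "NZPHa" = 195789152,
  " JtñQgàéiqh" = 389317436, "VJ" = 1593458969,
  "rsM" = 769416717, "TvnR" = 1793787603,
  "'qGFqèü'dfO" = 3019923859, "&rcavXi" = 459336910,
  "qkVCJTBJahe" = 3517843400, "èjIc&xLJjBic" = 3753950100,
  "xèñY-" = 1607940382, "è" = 496887598,
  "nRpQgw" = 3213904404, "é-ANVjññp" = 2692560093,
  "ZZl" = 334283035, "blVñvYñ" = 2391693810,
  "ZQ-VZpr" = 2863483669, "YSg" = 2805755014, "-c'Eom " = 1621516379,
  "wt Y-oob" = 2771512888, "mzvr-eXrwPG" = 2233996198,
  "R&Ivàbh" = 3352846651, "lLqcg" = 3280610942,
  "BwUYuBMGhy" = 1747136864, "mqcTBaHñZI" = 1348509510,
  "UàVVQmxBeàQ" = 4001429360, "NuQ'hU" = 276815095,
  "GtQAu" = 2892692923, "SsJimAQ" = 2429697907,
  "RVèlNKt" = 4175992019, "J&atsnB" = 1206476657,
  "MPuDCCRnGE" = 1299085819, "kQfsGQONvf à" = 3959384194,
  "RtoZ" = 641309162, "jbcp" = 1690657646,
  "N'XeDAéO" = 3434711883))

# random word generator for property tests
random_word <- function(max_len = 12) {
  chars <- c(letters, LETTERS, " ", "&", "'", "-")
  paste(sample(chars, sample.int(max_len, 1), replace = TRUE), collapse = "")
}

# tiny deterministic station frame
toy_stations <- function(n, city = "toy", prefix = "st") {
  data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
             name = sprintf("%s%03d", toupper(prefix), seq_len(n)),
             city = city,
             lat = seq(51, 51.5, length.out = n),
             lon = seq(-0.3, 0.2, length.out = n),
             stringsAsFactors = FALSE)
}
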