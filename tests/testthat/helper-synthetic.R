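## shared fixture builders (everything generated in code)

standardCellSpec <- function(noiseSd = 0, seed = 7L,
                             lengths = c(20, 30, 40, 25, 35)) {
  syntheticCellSpec(
    filopodia = data.frame(angle = c(0.3, 1.5, 2.8, 4.0, 5.3)[
                             seq_along(lengths)],
                           lengthPx = lengths, widthPx = 2,
                           intensity = 0.9),
    noiseSd = noiseSd, seed = seed)
}

discMask <- function(n, radius, center = (n + 1) / 2, spacing = 1) {
  R <- matrix(seq_len(n), n, n)
  C <- t(R)
  BinaryMask((R - center)^2 + (C - center)^2 <= radius^2,
             spacing = spacing)
}

ellipseMask <- function(n, a, b, spacing = 1) {
  ctr <- (n + 1) / 2
  R <- matrix(seq_len(n), n, n)
  C <- t(R)
  BinaryMask(((R - ctr) / a)^2 + ((C - ctr) / b)^2 <= 1,
             spacing = spacing)
}

## tiny simulation config for fast unit runs
tinySimConfig <- function(...) {
  simConfig(domainWidth = 120, domainHeight = 120, durationMin = 1,
            pFilo = 0.3, pInsert = 0.02, pMigrate = 0.1, pDecay = 0.05,
            initialBandUm = 50, ...)
}
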