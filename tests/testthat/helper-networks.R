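## Small networks built in code for solver and topology tests.

single_vessel_net <- function(radius = 0.3, length = 10, R1 = 5, R2 = 50,
                              C = 0.01, taper_to = radius, gamma_im = 0) {
  coronary_network(
    segments = vessel_segment("V", length, radius, taper_to,
                              territory = "systemic"),
    terminals = windkessel_terminal("t", "V", R1, R2, C, "systemic",
                                    gamma_im),
    inflows = data.frame(segment = "V", end = "proximal"))
}

symmetric_bifurcation_net <- function() {
  segs <- rbind(
    vessel_segment("P", 5, 0.3, 0.3, territory = "systemic"),
    vessel_segment("C1", 5, 0.2, 0.2, territory = "systemic"),
    vessel_segment("C2", 5, 0.2, 0.2, territory = "systemic"))
  jn <- data.frame(junction = "J1", segment = c("P", "C1", "C2"),
                   end = c("distal", "proximal", "proximal"))
  ter <- rbind(
    windkessel_terminal("t1", "C1", 5, 60, 0.005, "systemic", 0),
    windkessel_terminal("t2", "C2", 5, 60, 0.005, "systemic", 0))
  coronary_network(segments = segs, junctions = jn, terminals = ter,
                   inflows = data.frame(segment = "P", end = "proximal"))
}

## three-child junction with unequal children (mass-balance property)
trifurcation_net <- function() {
  segs <- rbind(
    vessel_segment("P", 5, 0.3, 0.3, territory = "systemic"),
    vessel_segment("C1", 5, 0.22, 0.2, territory = "systemic"),
    vessel_segment("C2", 4, 0.15, 0.12, territory = "systemic"),
    vessel_segment("C3", 6, 0.1, 0.08, territory = "systemic"))
  jn <- data.frame(junction = "J1",
                   segment = c("P", "C1", "C2", "C3"),
                   end = c("distal", rep("proximal", 3)))
  ter <- rbind(
    windkessel_terminal("t1", "C1", 5, 50, 0.005, "systemic", 0),
    windkessel_terminal("t2", "C2", 10, 120, 0.002, "systemic", 0),
    windkessel_terminal("t3", "C3", 20, 300, 0.001, "systemic", 0))
  coronary_network(segments = segs, junctions = jn, terminals = ter,
                   inflows = data.frame(segment = "P", end = "proximal"))
}

## independent trapezoid integration (test-side oracle)
trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

mean_aortic_pressure <- function(net) {
  g <- net$globals
  mean(eval_waveform(g$aortic, seq(0, g$period, length.out = 4096L)))
}
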