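# Builds the bundled motif model files under inst/extdata/models/.
# Run from the repo root: Rscript scratch/make_fixtures.R
suppressMessages({library(jsonlite)})
source("R/model.R"); source("R/io.R"); source("R/reachability.R")
dir.create("inst/extdata/models", recursive = TRUE, showWarnings = FALSE)

ns <- function(...) do.call(rbind, list(...))

# abc_example: A -> B (0.5) vs C -| B (0.4)
abc <- network_model(
  ns(node_spec("A", initial = 100L), node_spec("B"), node_spec("C", initial = 100L)),
  ns(edge_spec("A", "B", "activation", 1L, 0.5),
     edge_spec("C", "B", "inhibition", 1L, 0.4)),
  metadata = list(name = "abc_example",
                  description = "two-regulator race: net rate +0.1 on B when both regulators are full"))
save_model(abc, "inst/extdata/models/abc_example.json")

# ras_motif: 4 independent activators k=0.444 + self-inhibition k=1.0
ras <- network_model(
  ns(node_spec("Wnt"), node_spec("BMP"), node_spec("FGFR1"),
     node_spec("FGFR3"), node_spec("Ras")),
  ns(edge_spec("Wnt", "Ras", "activation", 1L, 0.444),
     edge_spec("BMP", "Ras", "activation", 1L, 0.444),
     edge_spec("FGFR1", "Ras", "activation", 1L, 0.444),
     edge_spec("FGFR3", "Ras", "activation", 1L, 0.444),
     edge_spec("Ras", "Ras", "inhibition", 1L, 1.0)),
  metadata = list(name = "ras_motif",
                  description = "additive-OR hub: one activator at 100 -> Ras attractor level 44"))
save_model(ras, "inst/extdata/models/ras_motif.json")

# and_gate: scenario-3 pair
andg <- network_model(
  ns(node_spec("A"), node_spec("B"), node_spec("C")),
  ns(edge_spec("A", "C", "activation", 3L, 1.0, reg2 = "B"),
     edge_spec("C", "C", "inhibition", 1L, 1.0)),
  metadata = list(name = "and_gate"))
save_model(andg, "inst/extdata/models/and_gate.json")

# destruction_complex: steady output (1 - Dsh) * min(1.5 - ERK, 1)
dc <- network_model(
  ns(node_spec("Dsh"), node_spec("ERK"),
     node_spec("DC_dummy", clamp = 100L),
     node_spec("DC_canonical"), node_spec("DC_degradation"),
     node_spec("DC")),
  ns(edge_spec("DC_dummy", "DC_canonical", "activation", 1L, 1.0),
     edge_spec("Dsh", "DC_canonical", "inhibition", 1L, 1.0),
     edge_spec("DC_canonical", "DC_canonical", "inhibition", 1L, 1.0),
     edge_spec("DC_dummy", "DC_degradation", "activation", 1L, 1.5),
     edge_spec("ERK", "DC_degradation", "inhibition", 1L, 1.0),
     edge_spec("DC_degradation", "DC_degradation", "inhibition", 1L, 1.0),
     edge_spec("DC_canonical", "DC", "activation", 3L, 1.0, reg2 = "DC_degradation"),
     edge_spec("DC", "DC", "inhibition", 1L, 1.0)),
  metadata = list(name = "destruction_complex",
                  description = paste(
                    "dummy-node subnetwork: DC_canonical settles at 1-Dsh,",
                    "DC_degradation saturates at min(1.5-ERK, 1), their",
                    "scenario-3 product drives DC")))
save_model(dc, "inst/extdata/models/destruction_complex.json")

# delayed_switch: T latches only if IGF is clamped on after the PRE
# transient has passed (immediate addition latches the blocker B instead).
dsw <- network_model(
  ns(node_spec("PRE", initial = 100L), node_spec("GATE"), node_spec("IGF"),
     node_spec("B"), node_spec("T")),
  ns(edge_spec("PRE", "PRE", "inhibition", 1L, 1.0),
     edge_spec("PRE", "GATE", "activation", 1L, 1.0),
     edge_spec("GATE", "GATE", "inhibition", 1L, 0.1),
     edge_spec("IGF", "B", "activation", 3L, 3.0, reg2 = "PRE"),
     edge_spec("B", "B", "activation", 3L, 2.0, reg2 = "B"),
     edge_spec("B", "B", "inhibition", 1L, 1.0),
     edge_spec("IGF", "T", "activation", 3L, 1.5, reg2 = "GATE"),
     edge_spec("T", "T", "activation", 3L, 2.0, reg2 = "T"),
     edge_spec("B", "T", "inhibition", 1L, 3.0),
     edge_spec("T", "T", "inhibition", 1L, 1.0)),
  metadata = list(name = "delayed_switch",
                  target_predicate = "T >= 60",
                  description = paste(
                    "reach 'T >= 60' by clamping IGF=100: impossible",
                    "immediately (blocker B latches via the fast PRE",
                    "transient), possible at later event indices while the",
                    "slow GATE is still up, impossible again once GATE has",
                    "decayed")))
save_model(dsw, "inst/extdata/models/delayed_switch.json")

# mini_chondro: 12-node tri-stable mutual-inhibition network (synthetic
# stand-in; attractors X+, Y+, Null, mutually exclusive).
side <- function(x, ax, s1, s2, mk, ck, other) {
  ns(edge_spec(ax, x, "activation", 3L, 1.6, reg2 = x),   # cooperative loop
     edge_spec(ax, x, "activation", 1L, 0.2),             # ignition
     edge_spec(other, x, "inhibition", 1L, 4.0),          # mutual inhibition
     edge_spec(x, x, "inhibition", 1L, 1.0),
     edge_spec(x, ax, "activation", 1L, 1.0),             # maintenance
     edge_spec(s1, ax, "activation", 1L, 0.25),
     edge_spec(s2, ax, "activation", 1L, 0.25),
     edge_spec(ax, ax, "inhibition", 1L, 1.0),
     edge_spec(s1, s1, "inhibition", 1L, 0.1),
     edge_spec(s2, s2, "inhibition", 1L, 0.1),
     edge_spec(x, mk, "activation", 1L, 1.0),             # markers
     edge_spec(mk, mk, "inhibition", 1L, 0.1),
     edge_spec(mk, ck, "activation", 1L, 0.5),
     edge_spec(ck, ck, "inhibition", 1L, 0.1))
}
mc <- network_model(
  ns(node_spec("X"), node_spec("Y"), node_spec("AX"), node_spec("AY"),
     node_spec("SX1", reaction_class = "slow"),
     node_spec("SX2", reaction_class = "slow"),
     node_spec("SY1", reaction_class = "slow"),
     node_spec("SY2", reaction_class = "slow"),
     node_spec("MX", reaction_class = "slow"),
     node_spec("MY", reaction_class = "slow"),
     node_spec("CX", reaction_class = "slow"),
     node_spec("CY", reaction_class = "slow")),
  rbind(side("X", "AX", "SX1", "SX2", "MX", "CX", "Y"),
        side("Y", "AY", "SY1", "SY2", "MY", "CY", "X")),
  metadata = list(name = "mini_chondro",
                  description = paste(
                    "synthetic tri-stable mutual-inhibition network:",
                    "masters X/Y sustained by cooperative feedback through",
                    "branch activators AX/AY, ignited by decaying signal",
                    "nodes, read out by downstream markers; attractors",
                    "X+, Y+ and Null")))
save_model(mc, "inst/extdata/models/mini_chondro.json")

cat("fixtures written\n")
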