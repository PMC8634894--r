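# Small models built in code, shared across test files.

nodes_of <- function(...) do.call(rbind, list(...))

# A -> B (k_act) vs C -| B (k_inh); A and C are input nodes.
two_regulator_race <- function(k_act = 0.5, k_inh = 0.4) {
  network_model(
    nodes_of(node_spec("A", initial = 100L), node_spec("B"),
             node_spec("C", initial = 100L)),
    rbind(edge_spec("A", "B", "activation", 1L, k_act),
          edge_spec("C", "B", "inhibition", 1L, k_inh)))
}

# hub with n_src independent activators (k_src) and a self-inhibition (k_self)
additive_hub <- function(n_src = 4L, k_src = 0.444, k_self = 1.0) {
  src <- paste0("S", seq_len(n_src))
  network_model(
    nodes_of(do.call(rbind, lapply(src, node_spec)), node_spec("hub")),
    rbind(do.call(rbind, lapply(src, function(s)
            edge_spec(s, "hub", "activation", 1L, k_src))),
          edge_spec("hub", "hub", "inhibition", 1L, k_self)))
}

decay_node <- function(init = 100L, k = 1.0) {
  network_model(node_spec("D", initial = init),
                edge_spec("D", "D", "inhibition", 1L, k))
}

# X -> prom -> prot chain with a self-inhibited pass-through node
prom_chain <- function() {
  network_model(
    nodes_of(node_spec("X"), node_spec("prom"), node_spec("prot")),
    rbind(edge_spec("X", "prom", "activation", 1L, 0.1),
          edge_spec("prom", "prom", "inhibition", 1L, 0.1),
          edge_spec("prom", "prot", "activation", 1L, 0.1),
          edge_spec("prot", "prot", "inhibition", 1L, 1.0)))
}

mini_chondro_classifier <- function() default_classifier("X", "Y")

is_self_inhibition_public <- function(edges) {
  edges$reg1 == edges$target & edges$sign == "inhibition" & edges$scenario != 3L
}
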