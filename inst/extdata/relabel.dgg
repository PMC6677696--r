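# two-state relabel model on a labeled pool graph
graph ab {
  lhs { 1 A }
  rhs { 1 B }
  rate 1
  cleanup full
}
graph ba {
  lhs { 1 B }
  rhs { 1 A }
  rate 0.5
  cleanup full
}
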