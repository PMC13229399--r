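# Example simulation design for `semgrn simulate --design ...`
# (all keys optional; these are the package defaults except for size)
p: 50
n: 200
topology: acyclic
edgeMean: 1.0
eePerGene: 1
errorModel: gaussian
errorSD: 0.1
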