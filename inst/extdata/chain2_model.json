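{"metabolites":"x1","reactions":["v1","v2"],"externals":["s_in","s_out"],"output_reaction":"v2","stoichiometry":[{"reaction":"v1","metabolite":"x1","coefficient":1},{"reaction":"v2","metabolite":"x1","coefficient":-1}],"state":[{"kind":"reaction","name":"v1","E0":1,"J0":1,"_row":"v1"},{"kind":"reaction","name":"v2","E0":1,"J0":1,"_row":"v2"},{"kind":"metabolite","name":"x1","x0":1,"_row":"x1"},{"kind":"external","name":"s_in","x0":1,"_row":"s_in"},{"kind":"external","name":"s_out","x0":1,"_row":"s_out"}],"elasticities":[{"reaction":"v1","metabolite":"x1","external":false,"value":-1},{"reaction":"v2","metabolite":"x1","external":false,"value":1},{"reaction":"v1","metabolite":"s_in","external":true,"value":1},{"reaction":"v2","metabolite":"s_out","external":true,"value":-1}]}
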