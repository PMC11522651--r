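BCT: {bct_label} = {bct_definition}
For example, {bct_examples}

Theoretical Constructs: {bct_theoretical_constructs}
Behavioral Strategies: {bct_behavioral_strategies}
{bct_label} is critical to each creative, chatty message.
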