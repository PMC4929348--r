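# Beneficial-effect textual patterns; '*' is a wildcard over 1..W tokens.
I use * for
I use it for
It helps with
It help with
I take it
I take it for
It works for
It is useful for
Useful for
Prescribed for
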