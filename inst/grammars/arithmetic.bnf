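<expr> ::= <binop>(<expr>, <expr>) | <term>
<binop> ::= add | sub | mul | div
<term> ::= <feature> | <const>
<const> ::= 0.1 | 0.2 | 0.3 | 0.4 | 0.5 | 0.6 | 0.7 | 0.8 | 0.9
<feature> ::= R0 | S | Rm | R4 | R20 | R4_R20 | Xm | Fr | Cdyn | Ax | Z4 | R | Rp | I | C | Rt
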