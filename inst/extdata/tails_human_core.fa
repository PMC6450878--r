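>ITGB1|762|Homo sapiens
EFAKFEKEKMNAKWDTGENPIYKSAVTTVVNPKYEGK
>ITGB2|734|Homo sapiens
EYRRFEKEKLKSQWNNDNPLFKSATTTVMNPKFAES
>ITGB3|752|Homo sapiens
EFAKFEEERARAKWDTANNPLYKEATSTFTNITYRGT
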