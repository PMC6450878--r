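>ITGB5|753|Homo sapiens
EFAKFQSERSRARYEMASNPLYRKPISTHTVDFTFNKFNKSYNGTVD
>ITGB6|741|Homo sapiens
EVAKFEAERSKAKWQTGTNPLYRGSTSTFKNVTYKHREKQKVDLSTDC
>ITGB7|753|Homo sapiens
YDRREYSRFEKEQQQLNWKQDSNPLYKSAITTTINPRFQEADSPTL
>ITGB8|744|Homo sapiens
EYRRFEKEKQQAKWQTDSNPLARSATSTFRSEDFRPS
>ITGB1_Cow|1|Capsaspora owczarzaki
EGRRFEREKQKAKWDTQENPIYKQATSTFKNPNYAGK
>ITGB2_Cow|1|Capsaspora owczarzaki
EGRKFELEKAKAKWDTADNPLFKEATSTFTNPKYSGT
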