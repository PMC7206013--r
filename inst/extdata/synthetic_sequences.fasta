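>atmc4_synthetic standin, K/R sites at documented positions
ASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFAHTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLCENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPRASTGVLDENRPFASTGVLDENQPFASTGVKDENQPFASTGVLDEKQPFASTGVLDEKQPFASTGVLDENQPFASTGVLDENQPFASKGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQ
>propep1_synthetic standin, R at 6/7/69
ASTGVRRENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDENQPFASTGVLDERQPFASTGVLDENQPFASTGVLDE
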