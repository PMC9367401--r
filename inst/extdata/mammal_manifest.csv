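class_name,images,training_instances,validation_instances
Bear,415,543,101
Cow,351,456,88
Cheetah,471,452,79
Deer,404,454,81
Elephant,404,595,100
Giraffe,438,520,79
Horse,400,482,82
Kangaroo,367,510,60
Koala,438,383,80
Lion,397,497,92
Tiger,399,413,72
Zebra,400,578,80
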