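quantity,value
registered_people,2645329
people_in_households_with_children,1022840
households_with_children,266939
other_households,245412
complex_households,21527
complex_people,89631
complex_children,41382
complex_adults,48249
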