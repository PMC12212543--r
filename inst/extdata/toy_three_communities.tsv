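# three 8-cliques bridged by a triangle between v01, v09, v17
v01	v02
v01	v03
v02	v03
v01	v04
v02	v04
v03	v04
v01	v05
v02	v05
v03	v05
v04	v05
v01	v06
v02	v06
v03	v06
v04	v06
v05	v06
v01	v07
v02	v07
v03	v07
v04	v07
v05	v07
v06	v07
v01	v08
v02	v08
v03	v08
v04	v08
v05	v08
v06	v08
v07	v08
v01	v09
v09	v10
v09	v11
v10	v11
v09	v12
v10	v12
v11	v12
v09	v13
v10	v13
v11	v13
v12	v13
v09	v14
v10	v14
v11	v14
v12	v14
v13	v14
v09	v15
v10	v15
v11	v15
v12	v15
v13	v15
v14	v15
v09	v16
v10	v16
v11	v16
v12	v16
v13	v16
v14	v16
v15	v16
v01	v17
v09	v17
v17	v18
v17	v19
v18	v19
v17	v20
v18	v20
v19	v20
v17	v21
v18	v21
v19	v21
v20	v21
v17	v22
v18	v22
v19	v22
v20	v22
v21	v22
v17	v23
v18	v23
v19	v23
v20	v23
v21	v23
v22	v23
v17	v24
v18	v24
v19	v24
v20	v24
v21	v24
v22	v24
v23	v24
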