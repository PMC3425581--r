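canonical,variant
atorvastatin,lipitor
atorvastatin,atorvastatin calcium
atorvastatin,atorvastatina
atorvastatin,atorvastatine
atorvastatin,atorvastatinum
atorvastatin,atorvastin
atorvastatin,atorvastatin
atorvastatin,torvast
atorvastatin,sortis
atorvastatin,tahor
simvastatin,zocor
simvastatin,simvastatina
simvastatin,simvastatine
simvastatin,simvastatinum
simvastatin,simvastin
simvastatin,simvistatin
simvastatin,zocord
simvastatin,simovil
simvastatin,denan
lovastatin,mevacor
lovastatin,lovastatina
lovastatin,lovastatine
lovastatin,lovastin
lovastatin,mevinolin
lovastatin,altoprev
pravastatin,pravachol
pravastatin,pravastatin sodium
pravastatin,pravastatina
pravastatin,pravastatine
pravastatin,pravastin
pravastatin,lipostat
pravastatin,selektine
pravastatin,elisor
rosuvastatin,crestor
rosuvastatin,rosuvastatin calcium
rosuvastatin,rosuvastatina
rosuvastatin,rosuvastatine
rosuvastatin,rosuvastin
rosuvastatin,rosuvastatinum
fluvastatin,lescol
fluvastatin,fluvastatin sodium
fluvastatin,fluvastatina
fluvastatin,fluvastatine
fluvastatin,fluvastin
fluvastatin,lescol xl
fluvastatin,canef
fluvastatin,vastin
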